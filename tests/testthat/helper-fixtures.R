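# Shared fixtures, memoized so expensive geometry is built once per run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

tg_mesh <- function(level = 2) {
  memo(paste0("mesh", level), make_sphere_mesh(level))
}

tg_grid <- function(spacing = 2.5) {
  memo(paste0("grid", spacing), make_seed_grid(spacing, c(13, 10, 7.5)))
}

tg_planted <- function(level = 2, spacing = 2.5, k = 3, noise_min = 0.25,
                       noise_max = 0.25) {
  memo(sprintf("planted_%s_%s_%s_%s_%s", level, spacing, k, noise_min,
               noise_max),
       plant_structure(tg_grid(spacing), tg_mesh(level), k = k,
                       noise_sd_at_min_age = noise_min,
                       noise_sd_at_max_age = noise_max))
}

# small raw matrix on the cortex of a mesh
tg_raw_matrix <- function(mesh, n_seeds = 3, seed = 1) {
  set.seed(seed)
  cortex <- cortex_indices(mesh)
  connectivity_matrix(matrix(runif(n_seeds * length(cortex)), n_seeds),
                      vertex_ids = cortex - 1L, state = "raw")
}

# random orthogonal k x k matrix (full O(k): reflections included)
random_orthogonal <- function(k) {
  qrd <- qr(matrix(rnorm(k * k), k))
  q <- qr.Q(qrd)
  d <- sign(diag(qr.R(qrd)))
  d[d == 0] <- 1
  q %*% diag(d, k)
}

# Moran lag-1 spatial autocorrelation over the cortex adjacency of a mesh
moran_lag1 <- function(values, mesh) {
  cortex <- cortex_indices(mesh)
  e <- thalagrad:::mesh_edges(mesh)
  e <- e[e[, 1] %in% cortex & e[, 2] %in% cortex, , drop = FALSE]
  i <- match(e[, 1], cortex)
  j <- match(e[, 2], cortex)
  z <- values - mean(values)
  w_total <- 2 * length(i)
  (length(z) / w_total) * (2 * sum(z[i] * z[j])) / sum(z^2)
}

# rotation-invariant smooth random field on the sphere: iid Gaussian
# coefficients on orthonormal real spherical harmonics (degrees 1 and 2)
# plus a little white noise. The harmonic normalization matters: within a
# degree the basis functions must have equal norm or the ensemble is
# anisotropic and spin nulls are no longer exchangeable.
smooth_sphere_map <- function(mesh, noise_sd = 0.1) {
  s <- mesh$sphere[cortex_indices(mesh), , drop = FALSE]
  x <- s[, 1]; y <- s[, 2]; z <- s[, 3]
  basis <- cbind(x, y, z,                                   # degree 1
                 x * y, x * z, y * z,                       # degree 2
                 (x^2 - y^2) / 2, (3 * z^2 - 1) / (2 * sqrt(3)))
  drop(basis %*% rnorm(ncol(basis))) + rnorm(nrow(s), sd = noise_sd)
}
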