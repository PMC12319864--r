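#' Plant a known low-rank gradient structure
#'
#' Constructs ground-truth component scores (over seeds) and loadings (over
#' non-medial-wall vertices) whose geometry mimics the gradients seen in
#' neonatal thalamocortical connectomes: component 1 varies along a combined
#' medial-lateral / anterior-posterior axis in the thalamus and along the
#' rostral-caudal (y) axis on the cortex; component 2 spreads radially from
#' a lateral anchor in the thalamus and dorso-ventrally on the cortex;
#' higher components are smooth low-order spatial harmonics. Score fields
#' are centred (zero mean over seeds) and both score and loading columns are
#' orthonormalized by an order-preserving Gram-Schmidt (QR), so planted
#' components are exactly recoverable by an SVD of the noise-free matrix.
#'
#' Component weights are scaled so the entry-level standard deviation of the
#' component-1 signal is ~1; noise standard deviations are therefore
#' expressed directly as fractions of the component-1 signal.
#'
#' @param seed_grid a [make_seed_grid()] object.
#' @param mesh a [make_sphere_mesh()] surface.
#' @param k number of planted components (1 to 5).
#' @param rng_seed integer seed; only consumed if the deterministic harmonic
#'   fields are rank-deficient for the given geometry and random smooth
#'   fields must top them up.
#' @param relative_weights positive, strictly decreasing weights, one per
#'   component, relative to component 1.
#' @param noise_sd_at_min_age,noise_sd_at_max_age subject noise standard
#'   deviation at the youngest / oldest scan age (fractions of the
#'   component-1 signal sd). The default decreasing profile makes younger
#'   subjects noisier, the generative assumption behind the
#'   similarity-vs-age analyses.
#' @return An object of class `planted_structure` with orthonormal
#'   `true_scores` (seeds x k), `true_loadings` (cortex vertices x k),
#'   strictly decreasing `component_weights`, the noise endpoints, and the
#'   cortex vertex indices the loadings refer to.
#' @export
plant_structure <- function(seed_grid, mesh, k = 3, rng_seed = 1,
                            relative_weights = c(1, 0.6, 0.3, 0.15, 0.08)[seq_len(k)],
                            noise_sd_at_min_age = 0.5,
                            noise_sd_at_max_age = 0.1) {
  stopifnot(inherits(seed_grid, "seed_grid"), inherits(mesh, "surface_mesh"))
  if (k < 1 || k > 5) stop("k must be between 1 and 5")
  cortex <- cortex_indices(mesh)
  n <- nrow(seed_grid$coordinates)
  m <- length(cortex)
  if (k > min(n, m))
    stop("k = ", k, " exceeds seed count (", n, ") or cortical vertex count (",
         m, ")")
  if (length(relative_weights) != k || any(relative_weights <= 0) ||
      any(diff(relative_weights) >= 0))
    stop("relative_weights must be ", k,
         " positive, strictly decreasing values")
  if (noise_sd_at_min_age < 0 || noise_sd_at_max_age < 0)
    stop("noise standard deviations must be non-negative")

  p <- seed_grid$coordinates
  anchor <- c(seed_grid$semi_axes[1], 0, 0)  # lateral anchor point
  zs <- function(x) if (stats::sd(x) == 0) x * 0 else (x - mean(x)) / stats::sd(x)
  score_fields <- cbind(
    zs(p[, 1]) - zs(p[, 2]),                       # medial-lateral + AP axis
    zs(-sqrt(rowSums(sweep(p, 2, anchor)^2))),     # radial from lateral anchor
    zs(p[, 3]),                                    # ventral-dorsal
    zs(p[, 1] * p[, 2]),                           # quadratic harmonics
    zs(p[, 1]^2 - p[, 2]^2))[, seq_len(k), drop = FALSE]
  s <- mesh$sphere[cortex, , drop = FALSE]
  loading_fields <- cbind(
    s[, 2],                                        # rostral-caudal
    s[, 3],                                        # dorso-ventral
    s[, 1],                                        # medial-lateral
    s[, 1] * s[, 2],
    3 * s[, 3]^2 - 1)[, seq_len(k), drop = FALSE]

  score_fields <- sweep(score_fields, 2, colMeans(score_fields))
  true_scores <- orthonormalize(score_fields, rng_seed)
  true_loadings <- orthonormalize(loading_fields, rng_seed + 1L)

  structure(list(true_scores = true_scores,
                 true_loadings = true_loadings,
                 component_weights = sqrt(n * m) * relative_weights,
                 noise_sd_at_min_age = noise_sd_at_min_age,
                 noise_sd_at_max_age = noise_sd_at_max_age,
                 cortex_vertices = cortex,
                 k = k),
            class = "planted_structure")
}

# Order-preserving Gram-Schmidt with sign fixed to correlate positively with
# the input column. Falls back to seeded random fields on rank deficiency.
orthonormalize <- function(fields, rng_seed) {
  qrd <- qr(fields)
  if (qrd$rank < ncol(fields)) {
    set.seed(rng_seed)
    fields <- fields + matrix(stats::rnorm(length(fields), sd = 1e-6),
                              nrow(fields))
    qrd <- qr(fields)
    if (qrd$rank < ncol(fields))
      stop("planted fields are rank deficient for this geometry")
  }
  q <- qr.Q(qrd)
  flip <- sign(diag(qr.R(qrd)))
  flip[flip == 0] <- 1
  q * rep(flip, each = nrow(q))
}

#' @export
print.planted_structure <- function(x, ...) {
  cat(sprintf(
    "<planted_structure> k = %d, %d seeds x %d cortical vertices\n",
    x$k, nrow(x$true_scores), nrow(x$true_loadings)))
  cat(sprintf("  weights: %s; noise sd %.3g (youngest) -> %.3g (oldest)\n",
              paste(signif(x$component_weights, 3), collapse = ", "),
              x$noise_sd_at_min_age, x$noise_sd_at_max_age))
  invisible(x)
}
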