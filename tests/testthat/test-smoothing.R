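test_that("a vanishing FWHM gives the identity kernel", {
  mesh <- tg_mesh(1)
  k <- build_kernel(mesh, fwhm = 1e-4, epsilon = 0.01)
  expect_equal(as.matrix(k$weights), diag(nrow(k$weights)),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("kernel rows always sum to one and diagonal is positive", {
  for (fwhm in c(3, 15, 40)) {
    k <- build_kernel(tg_mesh(2), fwhm = fwhm, epsilon = 0.01)
    expect_equal(Matrix::rowSums(k$weights),
                 rep(1, nrow(k$weights)), tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_true(all(Matrix::diag(k$weights) > 0))
  }
})

test_that("kernel matches a hand-computed Gaussian over brute-force paths", {
  mesh <- make_sphere_mesh(0, medial_angle = 0)  # 12 vertices, no wall
  edge_len <- sqrt(sum((mesh$vertices[1, ] - mesh$vertices[2, ])^2))
  # brute-force Floyd-Warshall on the icosahedron edge graph
  e <- thalagrad:::mesh_edges(mesh)
  d <- matrix(Inf, 12, 12)
  diag(d) <- 0
  len <- sqrt(rowSums((mesh$vertices[e[, 1], ] - mesh$vertices[e[, 2], ])^2))
  d[e] <- len
  d[e[, 2:1]] <- len
  for (mid in 1:12) for (i in 1:12) for (j in 1:12)
    if (d[i, mid] + d[mid, j] < d[i, j]) d[i, j] <- d[i, mid] + d[mid, j]
  fwhm <- edge_len
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  w <- exp(-d^2 / (2 * sigma^2))
  w[w < 0.01] <- 0
  w <- w / rowSums(w)
  k <- build_kernel(mesh, fwhm = fwhm, epsilon = 0.01)
  expect_equal(as.matrix(k$weights), w, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("medial wall exclusion never disconnects a level-2+ cortex", {
  expect_silent(build_kernel(tg_mesh(2), fwhm = 3))
})

test_that("smoothing conserves each seed's total connectivity", {
  mesh <- tg_mesh(2)
  k <- build_kernel(mesh, fwhm = 20, epsilon = 0.001)
  m <- tg_raw_matrix(mesh, n_seeds = 4, seed = 5)
  sm <- smooth_connectome(m, k)
  expect_equal(rowSums(sm$values), rowSums(m$values), tolerance = 1e-6)
  expect_true(all(sm$values >= 0))
  expect_equal(sm$state, "smoothed")
  # single-nonzero row: total preserved
  one <- connectivity_matrix(
    rbind(tabulate(3, ncol(m$values)) * 2.5),
    vertex_ids = m$vertex_ids, state = "raw")
  expect_equal(sum(smooth_connectome(one, k)$values), 2.5, tolerance = 1e-8)
})

test_that("identity and uniform kernels are the two limiting cases", {
  mesh <- tg_mesh(1)
  m <- tg_raw_matrix(mesh, n_seeds = 3, seed = 7)
  nv <- ncol(m$values)
  ident <- build_kernel(mesh, fwhm = 1e-4)
  expect_equal(smooth_connectome(m, ident)$values, m$values,
               tolerance = 1e-10)
  unif <- ident
  unif$weights <- Matrix::Matrix(1 / nv, nv, nv, sparse = TRUE)
  sm <- smooth_connectome(m, unif)
  expect_equal(sm$values, matrix(rowMeans(m$values), 3, nv),
               tolerance = 1e-12)
})

test_that("state and dimension mismatches are rejected", {
  mesh <- tg_mesh(1)
  k <- build_kernel(mesh, fwhm = 5)
  m <- tg_raw_matrix(mesh)
  sm <- smooth_connectome(m, k)
  expect_error(smooth_connectome(sm, k), "raw")
  k2 <- build_kernel(tg_mesh(2), fwhm = 5)
  expect_error(smooth_connectome(m, k2), "match")
  expect_error(build_kernel(mesh, fwhm = 0), "positive")
  expect_error(build_kernel(mesh, fwhm = 3, epsilon = 1), "epsilon")
})

test_that("optional seed-side smoothing conserves vertex totals", {
  grid <- make_seed_grid(2.5, c(6, 5, 4))
  mesh <- tg_mesh(1)
  set.seed(2)
  m <- connectivity_matrix(
    matrix(runif(nrow(grid$coordinates) * length(cortex_indices(mesh))),
           nrow(grid$coordinates)),
    vertex_ids = cortex_indices(mesh) - 1L, state = "raw")
  sm <- smooth_seeds(m, grid, fwhm = 6)
  expect_equal(colSums(sm$values), colSums(m$values), tolerance = 1e-8)
})
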