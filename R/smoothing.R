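#' Surface Gaussian smoothing kernel
#'
#' Builds the vertex-by-vertex smoothing kernel used for connectome spatial
#' smoothing. Geodesic distances between non-medial-wall vertices are
#' approximated by shortest paths on the mesh edge graph with Euclidean
#' (white-surface) edge lengths; each pair receives Gaussian weight
#' `exp(-d^2 / (2 sigma^2))` with `sigma = fwhm / (2 sqrt(2 ln 2))`, weights
#' below `epsilon` are truncated to exactly zero, and each row is then
#' renormalized to sum to one.
#'
#' @param mesh a `surface_mesh`.
#' @param fwhm kernel full width at half maximum, mm (> 0). Default 3.
#' @param epsilon truncation threshold applied to the raw Gaussian weight
#'   before row normalization, in \[0, 1). Default 0.01.
#' @return An object of class `smoothing_kernel`: `weights` (sparse
#'   row-stochastic matrix over non-medial-wall vertices), `fwhm`,
#'   `epsilon`, `vertex_ids` (0-based).
#' @export
build_kernel <- function(mesh, fwhm = 3, epsilon = 0.01) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (fwhm <= 0) stop("fwhm must be positive")
  if (epsilon < 0 || epsilon >= 1) stop("epsilon must be in [0, 1)")
  cortex <- cortex_indices(mesh)
  g <- cortex_graph(mesh)
  d <- igraph::distances(g)
  if (any(!is.finite(d)))
    stop("mesh has a disconnected non-medial-wall component; ",
         "geodesic distances are undefined")
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  w <- exp(-d^2 / (2 * sigma^2))
  w[w < epsilon] <- 0
  w <- w / rowSums(w)  # diagonal is exp(0) = 1 >= epsilon, so rows never empty
  structure(list(weights = Matrix::drop0(Matrix::Matrix(w, sparse = TRUE)),
                 fwhm = fwhm, epsilon = epsilon,
                 vertex_ids = cortex - 1L),
            class = "smoothing_kernel")
}

#' @export
print.smoothing_kernel <- function(x, ...) {
  cat(sprintf(
    "<smoothing_kernel> %d vertices, fwhm = %.3g mm, epsilon = %.3g, %.2f%% nonzero\n",
    nrow(x$weights), x$fwhm, x$epsilon,
    100 * Matrix::nnzero(x$weights) / prod(dim(x$weights))))
  invisible(x)
}

#' Smooth a connectome across the cortical dimension
#'
#' Applies the smoothing kernel over the cortical-vertex dimension only:
#' `smoothed = M %*% W`, which redistributes each vertex's connectivity over
#' its neighbourhood according to the kernel row. Because the kernel is
#' row-stochastic, each seed's total connectivity is conserved exactly and
#' non-negativity is preserved. The thalamic (seed) dimension is not
#' smoothed by default; see [smooth_seeds()] for the optional volumetric
#' seed-side kernel.
#'
#' @param matrix a [connectivity_matrix()] in state `"raw"`.
#' @param kernel a [build_kernel()] object on the same vertices.
#' @return A `connectivity_matrix` in state `"smoothed"`.
#' @export
smooth_connectome <- function(matrix, kernel) {
  stopifnot(inherits(matrix, "connectivity_matrix"),
            inherits(kernel, "smoothing_kernel"))
  if (matrix$state != "raw")
    stop("smooth_connectome expects a raw matrix, got state '",
         matrix$state, "'")
  if (ncol(matrix$values) != nrow(kernel$weights) ||
      !identical(matrix$vertex_ids, kernel$vertex_ids))
    stop("kernel vertex dimension does not match the connectivity matrix")
  smoothed <- as.matrix(matrix$values %*% kernel$weights)
  connectivity_matrix(pmax(smoothed, 0), seed_ids = matrix$seed_ids,
                      vertex_ids = matrix$vertex_ids, state = "smoothed")
}

#' Optional volumetric smoothing across thalamic seeds
#'
#' Connectome spatial smoothing is defined with one kernel per connection
#' endpoint; here the seed endpoint lives in thalamic volume rather than on
#' a mesh, so the seed-side kernel is a Euclidean-distance Gaussian over
#' seed coordinates. It is off by default in the pipeline: the cortical
#' kernel alone matches smoothing "across cortical vertices".
#'
#' @param matrix a `connectivity_matrix` (state `"raw"` or `"smoothed"`).
#' @param seed_grid the [make_seed_grid()] the rows refer to.
#' @param fwhm,epsilon as in [build_kernel()].
#' @return A `connectivity_matrix` with the same state progression as
#'   [smooth_connectome()] (`"raw"` input becomes `"smoothed"`).
#' @export
smooth_seeds <- function(matrix, seed_grid, fwhm = 3, epsilon = 0.01) {
  stopifnot(inherits(matrix, "connectivity_matrix"),
            inherits(seed_grid, "seed_grid"))
  if (!matrix$state %in% c("raw", "smoothed"))
    stop("seed smoothing applies to raw or smoothed matrices")
  if (nrow(matrix$values) != nrow(seed_grid$coordinates))
    stop("seed grid does not match the matrix rows")
  if (fwhm <= 0) stop("fwhm must be positive")
  p <- seed_grid$coordinates
  d2 <- outer(rowSums(p^2), rowSums(p^2), "+") - 2 * tcrossprod(p)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  w <- exp(-pmax(d2, 0) / (2 * sigma^2))
  w[w < epsilon] <- 0
  w <- w / rowSums(w)
  connectivity_matrix(pmax(crossprod(w, matrix$values), 0),
                      seed_ids = matrix$seed_ids,
                      vertex_ids = matrix$vertex_ids,
                      state = "smoothed")
}
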