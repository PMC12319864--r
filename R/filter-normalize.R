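#' Identify seeds with adequate cortical connectivity
#'
#' Deep (especially medial) thalamic seeds are hard to track from, and their
#' near-empty connectivity rows would otherwise dominate a decomposition
#' with noise. Given the across-subject mean of the smoothed matrices, a
#' seed is retained iff its row has at least `min_connected_vertices`
#' strictly positive entries. The retained index set is then applied
#' uniformly to every subject (see [subset_seeds()]).
#'
#' @param group_mean_matrix the elementwise mean of the cohort's smoothed
#'   connectivity matrices.
#' @param min_connected_vertices minimum number of connected (> 0) vertices
#'   a seed must reach. Default 100: seeds connected to fewer than 100
#'   vertices are removed.
#' @return Sorted integer vector of retained seed row indices (1-based).
#' @export
filter_seeds <- function(group_mean_matrix, min_connected_vertices = 100) {
  stopifnot(inherits(group_mean_matrix, "connectivity_matrix"))
  if (min_connected_vertices < 0)
    stop("min_connected_vertices must be non-negative")
  counts <- unname(rowSums(group_mean_matrix$values > 0))
  retained <- which(counts >= min_connected_vertices)
  if (length(retained) == 0)
    stop("all ", length(counts), " seeds fall below the ",
         min_connected_vertices, "-vertex connectivity threshold")
  message(length(counts) - length(retained), " of ", length(counts),
          " seeds removed (connected to < ", min_connected_vertices,
          " vertices); ", length(retained), " retained")
  sort(retained)
}

#' Elementwise mean of a list of connectivity matrices
#'
#' @param matrices list of [connectivity_matrix()] objects sharing
#'   dimensions, ids and state.
#' @return A `connectivity_matrix` of the same state.
#' @export
mean_matrix <- function(matrices) {
  if (length(matrices) == 0) stop("empty matrix list")
  first <- matrices[[1]]
  for (mat in matrices) {
    stopifnot(inherits(mat, "connectivity_matrix"))
    if (!identical(dim(mat$values), dim(first$values)) ||
        !identical(mat$seed_ids, first$seed_ids) ||
        !identical(mat$vertex_ids, first$vertex_ids))
      stop("matrices do not share seed/vertex structure")
    if (!identical(mat$state, first$state))
      stop("matrices are in different processing states")
  }
  avg <- Reduce(`+`, lapply(matrices, `[[`, "values")) / length(matrices)
  connectivity_matrix(avg, seed_ids = first$seed_ids,
                      vertex_ids = first$vertex_ids, state = first$state)
}

#' Scaled sigmoid normalization of cortical connectivity
#'
#' Normalizes each vertex's connectivity profile across thalamic seeds to
#' \[0, 1\] in two steps. First the sigmoid
#' \deqn{S(x) = 1 / (1 + \exp(-(x - \langle x\rangle)/\sigma_x))}
#' is applied per vertex column, where \eqn{\langle x\rangle} and
#' \eqn{\sigma_x} are the mean and (population, divide-by-n) standard
#' deviation of that connection's values across seeds; then each column is
#' linearly rescaled so its minimum maps to 0 and its maximum to 1. The
#' transform is monotone within every column and damps the influence of
#' outlying connection weights. Columns with \eqn{\sigma_x = 0} (where the
#' sigmoid is undefined) are set to the constant 0.5, its symmetric limit.
#'
#' @param matrix a `connectivity_matrix` in state `"smoothed"` or
#'   `"filtered"` with at least two seeds.
#' @return A list with `matrix` (state `"normalized"`) and `params`, a
#'   `normalization_params` object holding per-vertex `mean`, `sd` and the
#'   post-sigmoid `min`/`max` used for the linear rescale.
#' @export
normalize_sigmoid <- function(matrix) {
  stopifnot(inherits(matrix, "connectivity_matrix"))
  if (!matrix$state %in% c("smoothed", "filtered"))
    stop("normalize_sigmoid expects a smoothed or filtered matrix, got '",
         matrix$state, "'")
  x <- matrix$values
  if (nrow(x) < 2) stop("normalization needs at least 2 seeds")
  mu <- colMeans(x)
  sd_pop <- sqrt(colMeans(sweep(x, 2, mu)^2))
  const <- sd_pop == 0
  safe_sd <- ifelse(const, 1, sd_pop)
  s <- 1 / (1 + exp(-sweep(sweep(x, 2, mu), 2, safe_sd, "/")))
  smin <- apply(s, 2, min)
  smax <- apply(s, 2, max)
  rng <- smax - smin
  rng[rng == 0] <- 1
  out <- sweep(sweep(s, 2, smin), 2, rng, "/")
  out[, const] <- 0.5
  params <- structure(list(mean = mu, sd = sd_pop, min = smin, max = smax,
                           vertex_ids = matrix$vertex_ids),
                      class = "normalization_params")
  list(matrix = connectivity_matrix(out, seed_ids = matrix$seed_ids,
                                    vertex_ids = matrix$vertex_ids,
                                    state = "normalized"),
       params = params)
}
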