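#' Seed-by-vertex connectivity matrix
#'
#' Container for a dense structural connectome: non-negative connection
#' weights between thalamic seeds (rows) and cortical surface vertices
#' (columns), together with seed/vertex identifiers and a processing-state
#' tag that records how far along the build pipeline the matrix is.
#'
#' States form a pipeline: `"raw"` (summed streamline FA weights) ->
#' `"smoothed"` (surface Gaussian smoothing) -> `"filtered"`
#' (low-connectivity seeds removed) -> `"normalized"` (scaled sigmoid,
#' values in \[0, 1\]) -> `"centred"` (per-vertex mean removed; the only
#' state allowed to contain negative values).
#'
#' @param values numeric matrix, seeds x vertices.
#' @param seed_ids integer identifiers, one per row (0-based in all
#'   serialized outputs; any unique integers accepted here).
#' @param vertex_ids integer identifiers, one per column.
#' @param state processing state, one of `"raw"`, `"smoothed"`,
#'   `"filtered"`, `"normalized"`, `"centred"`.
#' @return An object of class `connectivity_matrix`.
#' @export
connectivity_matrix <- function(values, seed_ids = seq_len(nrow(values)) - 1L,
                                vertex_ids = seq_len(ncol(values)) - 1L,
                                state = "raw") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  dimnames(values) <- NULL
  state <- match.arg(state, c("raw", "smoothed", "filtered", "normalized",
                              "centred"))
  if (length(seed_ids) != nrow(values))
    stop("seed_ids length (", length(seed_ids), ") does not match row count (",
         nrow(values), ")")
  if (length(vertex_ids) != ncol(values))
    stop("vertex_ids length (", length(vertex_ids),
         ") does not match column count (", ncol(values), ")")
  if (anyDuplicated(seed_ids)) stop("duplicate seed ids")
  if (anyDuplicated(vertex_ids)) stop("duplicate vertex ids")
  if (anyNA(values)) stop("connectivity values contain NA")
  if (state %in% c("raw", "smoothed", "filtered") && any(values < 0))
    stop("state '", state, "' requires non-negative values")
  if (state == "normalized" && (any(values < -1e-12) || any(values > 1 + 1e-12)))
    stop("state 'normalized' requires values in [0, 1]")
  structure(
    list(values = values,
         seed_ids = as.integer(seed_ids),
         vertex_ids = as.integer(vertex_ids),
         state = state),
    class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix> %d seeds x %d vertices, state = '%s'\n",
              nrow(x$values), ncol(x$values), x$state))
  cat(sprintf("  weight range [%.4g, %.4g], %.1f%% nonzero\n",
              min(x$values), max(x$values),
              100 * mean(x$values != 0)))
  invisible(x)
}

#' @export
dim.connectivity_matrix <- function(x) dim(x$values)

#' Restrict a connectivity matrix to a subset of seeds
#'
#' Used to apply the retained-seed index set from [filter_seeds()] uniformly
#' to every subject of a cohort.
#'
#' @param matrix a [connectivity_matrix()].
#' @param seed_index integer row indices (1-based) to retain.
#' @return A `connectivity_matrix` with state `"filtered"` (if the input was
#'   `"raw"`, `"smoothed"` or `"filtered"`) or the input state otherwise.
#' @export
subset_seeds <- function(matrix, seed_index) {
  stopifnot(inherits(matrix, "connectivity_matrix"))
  if (length(seed_index) == 0) stop("empty seed index")
  if (any(seed_index < 1 | seed_index > nrow(matrix$values)))
    stop("seed index out of range")
  state <- if (matrix$state %in% c("raw", "smoothed", "filtered"))
    "filtered" else matrix$state
  connectivity_matrix(matrix$values[seed_index, , drop = FALSE],
                      seed_ids = matrix$seed_ids[seed_index],
                      vertex_ids = matrix$vertex_ids,
                      state = state)
}
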