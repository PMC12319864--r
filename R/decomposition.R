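#' Centre a connectivity matrix per vertex
#'
#' Subtracts each vertex column's across-seed mean, the standard centring
#' step before a principal-component decomposition. The removed means are
#' recorded so the original matrix can be recovered. Normalized input is
#' the usual pipeline state, but any common-scale matrix (smoothed,
#' filtered) is accepted: centring itself needs nothing more.
#'
#' @param matrix a `connectivity_matrix` in state `"normalized"`,
#'   `"smoothed"` or `"filtered"`.
#' @return A `connectivity_matrix` in state `"centred"`, with the removed
#'   per-vertex means in `$column_means`.
#' @export
center_matrix <- function(matrix) {
  stopifnot(inherits(matrix, "connectivity_matrix"))
  if (!matrix$state %in% c("normalized", "smoothed", "filtered"))
    stop("center_matrix expects a normalized (or smoothed/filtered) matrix, ",
         "got '", matrix$state, "'")
  mu <- colMeans(matrix$values)
  out <- connectivity_matrix(sweep(matrix$values, 2, mu),
                             seed_ids = matrix$seed_ids,
                             vertex_ids = matrix$vertex_ids,
                             state = "centred")
  out$column_means <- mu
  out
}

#' Principal component decomposition via SVD
#'
#' Thin singular value decomposition `M = U S V^T` of a centred
#' connectivity matrix, truncated to `k` components. Scores are `U S`
#' (one row per thalamic seed), loadings are the right singular vectors
#' (one row per cortical vertex), and the variance explained by component k
#' is `lambda_k = s_k^2 / (n - 1)` with n the seed count; fractions are
#' relative to the total variance over all components. The SVD sign
#' ambiguity is fixed by forcing each loading column's largest-magnitude
#' entry to be positive.
#'
#' @param matrix a `connectivity_matrix` in state `"centred"`.
#' @param k number of components to retain (1 to `min(n, m)`).
#' @return An object of class `decomposition`: `scores` (n x k), `loadings`
#'   (m x k), `singular_values` (k), `variance_explained` (k),
#'   `variance_fraction` (k), `total_variance`, `k`, `n_seeds`,
#'   `column_means`, `seed_ids`, `vertex_ids`.
#' @export
pca_svd <- function(matrix, k) {
  stopifnot(inherits(matrix, "connectivity_matrix"))
  if (matrix$state != "centred")
    stop("pca_svd expects a centred matrix; call center_matrix() first")
  n <- nrow(matrix$values)
  m <- ncol(matrix$values)
  if (k < 1 || k > min(n, m))
    stop("k must be between 1 and min(seeds, vertices) = ", min(n, m))
  sv <- svd(matrix$values)
  flip <- vapply(seq_len(k), function(j) {
    i <- which.max(abs(sv$v[, j]))
    if (sv$v[i, j] < 0) -1 else 1
  }, numeric(1))
  u <- sweep(sv$u[, seq_len(k), drop = FALSE], 2, flip, "*")
  v <- sweep(sv$v[, seq_len(k), drop = FALSE], 2, flip, "*")
  d <- sv$d[seq_len(k)]
  lambda_all <- sv$d^2 / (n - 1)
  structure(list(scores = u %*% diag(d, k),
                 loadings = v,
                 singular_values = d,
                 variance_explained = lambda_all[seq_len(k)],
                 variance_fraction = lambda_all[seq_len(k)] / sum(lambda_all),
                 total_variance = sum(lambda_all),
                 k = k,
                 n_seeds = n,
                 column_means = matrix$column_means,
                 seed_ids = matrix$seed_ids,
                 vertex_ids = matrix$vertex_ids),
            class = "decomposition")
}

#' @export
print.decomposition <- function(x, ...) {
  cat(sprintf("<decomposition> k = %d over %d seeds x %d vertices\n",
              x$k, nrow(x$scores), nrow(x$loadings)))
  cat("  variance fraction:",
      paste(sprintf("%.1f%%", 100 * x$variance_fraction), collapse = ", "),
      "\n")
  invisible(x)
}

#' Decompose a single matrix through the standard path
#'
#' Convenience wrapper: centre then [pca_svd()].
#'
#' @param matrix a `connectivity_matrix` accepted by [center_matrix()].
#' @param k components to retain.
#' @return A `decomposition`.
#' @export
decompose_matrix <- function(matrix, k) pca_svd(center_matrix(matrix), k)

#' Build the term template decomposition
#'
#' Selects the `n_template` oldest (by scan age) term-born subjects,
#' averages their connectivity matrices elementwise, and decomposes the
#' average matrix with exactly the same centring as individual matrices.
#' The resulting scores/loadings are the alignment reference ("term
#' template") for the cohort. A per-subject exclusion list supports
#' leave-one-out templates.
#'
#' @param matrices list of `connectivity_matrix`, one per phenotype row.
#' @param phenotypes data.frame with at least `subject_id`,
#'   `scan_age_weeks` and `group` columns.
#' @param n_template number of template subjects (default 20).
#' @param k components to retain.
#' @param exclude character vector of `subject_id`s to exclude from
#'   eligibility (e.g. the left-out subject), or `NULL`.
#' @return An object of class `template_bundle`: `mean_matrix`,
#'   `decomposition`, `subject_ids`.
#' @export
build_template <- function(matrices, phenotypes, n_template = 20, k = 5,
                           exclude = NULL) {
  if (length(matrices) != nrow(phenotypes))
    stop("one matrix per phenotype row required")
  eligible <- which(phenotypes$group == "term" &
                      !(phenotypes$subject_id %in% exclude))
  if (length(eligible) < n_template)
    stop("only ", length(eligible), " eligible term subjects; ",
         n_template, " needed for the template")
  chosen <- eligible[order(phenotypes$scan_age_weeks[eligible],
                           decreasing = TRUE)][seq_len(n_template)]
  avg <- mean_matrix(matrices[chosen])
  structure(list(mean_matrix = avg,
                 decomposition = decompose_matrix(avg, k),
                 subject_ids = phenotypes$subject_id[chosen]),
            class = "template_bundle")
}

#' @export
print.template_bundle <- function(x, ...) {
  cat(sprintf("<template_bundle> %d subjects averaged, k = %d\n",
              length(x$subject_ids), x$decomposition$k))
  invisible(x)
}
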