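#' Procrustes alignment of a decomposition to a template
#'
#' Solves the orthogonal Procrustes problem
#' \deqn{\min_R \| A R - B \|_F}
#' over orthogonal `R` (reflections permitted), where `A` holds the
#' individual's first `k_align` score columns (the `US` matrix) and `B` the
#' template's, via the closed-form SVD solution `R = P Q^T` with
#' `A^T B = P D Q^T`. The rotation derived from the scores is then applied
#' to both the scores and the loadings; no scaling and no translation are
#' applied. Reflections are allowed because sign flips between
#' independently computed SVDs are expected and a pure rotation could not
#' correct them.
#'
#' @param individual a [pca_svd()] decomposition with at least `k_align`
#'   components.
#' @param template the reference `decomposition` (same seed count).
#' @param k_align number of components used for (and carried through)
#'   alignment; default 5.
#' @return An object of class `aligned_decomposition`: `base` (the input),
#'   `rotation` (k_align x k_align orthogonal), `aligned_scores`,
#'   `aligned_loadings`, `k_align`.
#' @export
procrustes_align <- function(individual, template, k_align = 5) {
  stopifnot(inherits(individual, "decomposition"),
            inherits(template, "decomposition"))
  if (individual$k < k_align || template$k < k_align)
    stop("both decompositions need at least k_align = ", k_align,
         " components")
  if (nrow(individual$scores) != nrow(template$scores))
    stop("seed counts differ (", nrow(individual$scores), " vs ",
         nrow(template$scores), "); cannot align")
  a <- individual$scores[, seq_len(k_align), drop = FALSE]
  b <- template$scores[, seq_len(k_align), drop = FALSE]
  sv <- svd(crossprod(a, b))
  rot <- sv$u %*% t(sv$v)
  structure(list(base = individual,
                 rotation = rot,
                 aligned_scores = a %*% rot,
                 aligned_loadings =
                   individual$loadings[, seq_len(k_align), drop = FALSE] %*% rot,
                 k_align = k_align),
            class = "aligned_decomposition")
}

#' @export
print.aligned_decomposition <- function(x, ...) {
  cat(sprintf("<aligned_decomposition> k_align = %d, det(R) = %+.0f\n",
              x$k_align, det(x$rotation)))
  invisible(x)
}

#' Similarity of an aligned decomposition to the template
#'
#' Pearson correlation between one aligned component column and the
#' corresponding template column, computed over seeds (`domain = "scores"`)
#' or over non-medial-wall vertices (`domain = "loadings"`). This is the
#' per-subject summary used in the similarity-vs-age analyses.
#'
#' @param aligned an [procrustes_align()] result.
#' @param template the template `decomposition` it was aligned to.
#' @param component component index (<= `k_align`).
#' @param domain `"scores"` or `"loadings"`.
#' @return A single correlation, or `NA` (with a warning) if either column
#'   is constant.
#' @export
similarity_to_template <- function(aligned, template, component = 1,
                                   domain = c("scores", "loadings")) {
  stopifnot(inherits(aligned, "aligned_decomposition"),
            inherits(template, "decomposition"))
  domain <- match.arg(domain)
  if (component < 1 || component > aligned$k_align)
    stop("component must be between 1 and k_align = ", aligned$k_align)
  a <- if (domain == "scores") aligned$aligned_scores[, component]
       else aligned$aligned_loadings[, component]
  b <- if (domain == "scores") template$scores[, component]
       else template$loadings[, component]
  if (length(a) != length(b))
    stop("aligned and template ", domain, " have different lengths")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("constant ", domain, " column; similarity undefined")
    return(NA_real_)
  }
  stats::cor(a, b)
}
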