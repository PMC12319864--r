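#' Per-element statistical map
#'
#' Light container for seedwise or vertexwise statistics with their
#' p-values and a significance mask.
#'
#' @param statistic numeric vector of per-element statistics.
#' @param p raw p-values (same length, NA allowed).
#' @param p_adjusted multiplicity-adjusted p-values, or `NULL`.
#' @param mask logical significance mask, or `NULL`.
#' @param domain `"thalamus"` or `"cortex"`.
#' @param ids element identifiers (0-based seed or vertex ids).
#' @param threshold the significance level the mask was taken at.
#' @return An object of class `stat_map`.
#' @export
stat_map <- function(statistic, p = rep(NA_real_, length(statistic)),
                     p_adjusted = NULL, mask = NULL,
                     domain = c("cortex", "thalamus"),
                     ids = seq_along(statistic) - 1L, threshold = 0.05) {
  domain <- match.arg(domain)
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values outside [0, 1]")
  structure(list(statistic = statistic, p = p, p_adjusted = p_adjusted,
                 mask = mask, domain = domain, ids = as.integer(ids),
                 threshold = threshold),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("<stat_map> %d %s elements", length(x$statistic), x$domain))
  if (!is.null(x$mask))
    cat(sprintf(", %d significant at %.3g", sum(x$mask, na.rm = TRUE),
                x$threshold))
  cat("\n")
  invisible(x)
}

#' Benjamini-Hochberg false-discovery-rate control
#'
#' Step-up FDR adjustment of a p-value vector with a rejection mask at
#' level `q`. Missing p-values are excluded from the family and stay `NA`
#' in the output.
#'
#' @param p_values raw p-values in \[0, 1\] (NA allowed).
#' @param q target false-discovery rate (default 0.05).
#' @return A list with `p_adjusted` and logical `mask`.
#' @export
fdr_bh <- function(p_values, q = 0.05) {
  if (length(p_values) == 0)
    return(list(p_adjusted = numeric(0), mask = logical(0)))
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1))
    stop("p-values outside [0, 1]")
  adj <- rep(NA_real_, length(p_values))
  adj[ok] <- stats::p.adjust(p_values[ok], method = "BH")
  mask <- !is.na(adj) & adj <= q
  list(p_adjusted = adj, mask = mask)
}

#' Age-correlation map over seeds or vertices
#'
#' For every element (thalamic seed score or cortical vertex loading) of a
#' chosen aligned component, computes the Pearson correlation between that
#' element's value and scan age across subjects, with a two-sided p-value
#' from the t-distribution with n - 2 degrees of freedom and an FDR
#' rejection mask. Elements constant across subjects have no defined
#' correlation; they are recorded as `NA` and excluded from the FDR family.
#'
#' @param aligned_list list of [procrustes_align()] results, one per
#'   subject.
#' @param ages numeric scan ages, one per subject (>= 3 subjects).
#' @param component aligned component index.
#' @param domain `"scores"` (thalamic seeds) or `"loadings"` (cortical
#'   vertices).
#' @param q FDR level for the mask (default 0.05).
#' @return A [stat_map()] with `statistic` = r.
#' @export
age_correlation_map <- function(aligned_list, ages, component = 1,
                                domain = c("scores", "loadings"), q = 0.05) {
  domain <- match.arg(domain)
  n <- length(aligned_list)
  if (n != length(ages)) stop("one age per subject required")
  if (n < 3) stop("at least 3 subjects required")
  field <- if (domain == "scores") "aligned_scores" else "aligned_loadings"
  vals <- vapply(aligned_list, function(a) {
    stopifnot(inherits(a, "aligned_decomposition"))
    if (component > a$k_align)
      stop("component exceeds k_align = ", a$k_align)
    a[[field]][, component]
  }, numeric(nrow(aligned_list[[1]][[field]])))
  vals <- t(vals)  # subjects x elements
  sds <- apply(vals, 2, stats::sd)
  r <- rep(NA_real_, ncol(vals))
  nz <- sds > 0 & stats::sd(ages) > 0
  r[nz] <- as.vector(stats::cor(vals[, nz, drop = FALSE], ages))
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- ifelse(is.na(r), NA_real_, 2 * stats::pt(-abs(tt), df = n - 2))
  fdr <- fdr_bh(p, q)
  base <- aligned_list[[1]]$base
  stat_map(statistic = r, p = p, p_adjusted = fdr$p_adjusted,
           mask = fdr$mask,
           domain = if (domain == "scores") "thalamus" else "cortex",
           ids = if (domain == "scores") base$seed_ids else base$vertex_ids,
           threshold = q)
}

#' Correlation of per-seed values with a Cartesian axis
#'
#' Pearson correlation between a per-seed scalar (typically a component's
#' scores) and the seed coordinate along one axis: x = medial-lateral,
#' y = anterior-posterior, z = inferior-superior.
#'
#' @param values numeric vector, one per seed (aligned with the grid rows).
#' @param seed_grid the [make_seed_grid()] the values refer to; pass a
#'   seed-filtered grid subset via `seed_index` if seeds were removed.
#' @param axis `"x"`, `"y"` or `"z"`.
#' @param seed_index optional integer indices of the retained grid rows.
#' @return A list with `r` and `p` (two-sided).
#' @export
axis_correlation <- function(values, seed_grid, axis = c("x", "y", "z"),
                             seed_index = NULL) {
  stopifnot(inherits(seed_grid, "seed_grid"))
  axis <- match.arg(axis)
  coords <- seed_grid$coordinates
  if (!is.null(seed_index)) coords <- coords[seed_index, , drop = FALSE]
  if (length(values) != nrow(coords))
    stop("values (", length(values), ") do not match seed count (",
         nrow(coords), ")")
  ct <- stats::cor.test(values, coords[, match(axis, c("x", "y", "z"))])
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Total connectivity of each vertex to the thalamus
#'
#' Column sums over the retained seeds, i.e. each cortical vertex's summed
#' connectivity across thalamic seeds. Computed on the smoothed
#' (pre-sigmoid) matrix, whose weights are still on the streamline-FA
#' scale; optionally divided by the subject's grand total to give the
#' proportion of connectivity.
#'
#' @param matrix a `connectivity_matrix` in state `"smoothed"` or
#'   `"filtered"`.
#' @param proportion if `TRUE`, divide the totals by their sum.
#' @return Numeric vector, one total per vertex.
#' @export
vertex_totals <- function(matrix, proportion = FALSE) {
  stopifnot(inherits(matrix, "connectivity_matrix"))
  if (!matrix$state %in% c("smoothed", "filtered"))
    stop("vertex totals are computed before normalization (state smoothed ",
         "or filtered), got '", matrix$state, "'")
  tot <- colSums(matrix$values)
  if (proportion) {
    s <- sum(tot)
    if (s == 0) stop("all-zero matrix: proportions undefined")
    tot <- tot / s
  }
  tot
}
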