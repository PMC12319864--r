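#' Group-comparison design matrix
#'
#' Builds the design used for the preterm-vs-term comparisons: intercept,
#' group indicator (1 = the level named in `contrast_group`), scan age and
#' sex, with the contrast on the group column. The design must be full
#' column rank.
#'
#' @param phenotypes data.frame with `group`, `scan_age_weeks`, `sex`
#'   columns (e.g. a [simulate_cohort()] phenotype table), or any subset of
#'   subjects.
#' @param contrast_group group level coded 1 in the indicator (default
#'   `"preterm"`).
#' @return An object of class `glm_design`: `X` (n x 4), `contrast`
#'   (length 4), `group_col` (index of the permutable column).
#' @export
glm_design <- function(phenotypes, contrast_group = "preterm") {
  req <- c("group", "scan_age_weeks", "sex")
  if (!all(req %in% names(phenotypes)))
    stop("phenotypes must have columns ", paste(req, collapse = ", "))
  x <- cbind(intercept = 1,
             group = as.numeric(phenotypes$group == contrast_group),
             scan_age = phenotypes$scan_age_weeks,
             sex = as.numeric(phenotypes$sex == phenotypes$sex[1]))
  if (qr(x)$rank < ncol(x))
    stop("design matrix is rank deficient (a column is constant or ",
         "collinear)")
  structure(list(X = x, contrast = c(0, 1, 0, 0), group_col = 2L),
            class = "glm_design")
}

#' @export
print.glm_design <- function(x, ...) {
  cat(sprintf("<glm_design> %d subjects x %d columns (%s); contrast on '%s'\n",
              nrow(x$X), ncol(x$X), paste(colnames(x$X), collapse = ", "),
              colnames(x$X)[which(x$contrast != 0)]))
  invisible(x)
}

#' Vertexwise GLM t-statistics
#'
#' Ordinary-least-squares fit of every outcome column on the design, with
#' the two-tailed t-statistic for the contrast:
#' `t = c' beta / sqrt(sigma^2 c' (X'X)^{-1} c)` with residual degrees of
#' freedom `n - rank(X)`. Columns with (numerically) zero residual variance
#' produce infinite t and trigger a degenerate-fit warning.
#'
#' @param Y numeric matrix, subjects x vertices (or any outcomes).
#' @param design a [glm_design()] (or compatible list with `X` and
#'   `contrast`).
#' @return A [stat_map()] with `statistic` = t and two-sided p-values.
#' @export
glm_tmap <- function(Y, design) {
  Y <- as.matrix(Y)
  x <- design$X
  if (nrow(Y) != nrow(x)) stop("Y rows must match design rows")
  qx <- qr(x)
  if (qx$rank < ncol(x)) stop("design matrix is rank deficient")
  if (nrow(x) <= ncol(x)) stop("need more subjects than design columns")
  beta <- qr.coef(qx, Y)
  res <- Y - x %*% beta
  df <- nrow(x) - qx$rank
  sigma2 <- colSums(res^2) / df
  xtx_inv <- chol2inv(qr.R(qx))
  cvar <- drop(t(design$contrast) %*% xtx_inv %*% design$contrast)
  eff <- drop(t(design$contrast) %*% beta)
  se <- sqrt(sigma2 * cvar)
  degenerate <- sigma2 <= .Machine$double.eps * max(1, max(abs(Y))^2)
  if (any(degenerate))
    warning(sum(degenerate), " outcome column(s) have ~zero residual ",
            "variance; t is unbounded there (degenerate fit)")
  # degenerate columns: report unbounded t with the effect's sign
  tt <- ifelse(degenerate | se == 0,
               ifelse(eff == 0, 0, sign(eff) * Inf),
               eff / se)
  p <- 2 * stats::pt(-abs(tt), df = df)
  out <- stat_map(statistic = tt, p = p, domain = "cortex")
  out$df <- df
  out
}

#' Group effect on a per-subject scalar, controlling covariates
#'
#' Compares the covariates-only model (intercept + scan age + sex) against
#' the full model including the group indicator with a partial F-test
#' (numerator df 1, denominator df n - rank of the full design). Used to
#' ask whether a scalar summary such as a component's variance-explained
#' fraction differs between groups after controlling for scan age and sex.
#'
#' @param values numeric vector, one scalar per subject.
#' @param design a [glm_design()].
#' @return A list: `F`, `p`, `df1`, `df2`.
#' @export
group_scalar_ancova <- function(values, design) {
  x <- design$X
  if (length(values) != nrow(x)) stop("one value per subject required")
  if (nrow(x) <= ncol(x)) stop("need more subjects than design columns")
  if (qr(x)$rank < ncol(x)) stop("design matrix is rank deficient")
  covariates <- x[, -c(1, design$group_col), drop = FALSE]
  fit0 <- stats::lm(values ~ covariates)
  fit1 <- stats::lm(values ~ covariates + x[, design$group_col])
  df2 <- stats::df.residual(fit1)
  rss1 <- sum(stats::residuals(fit1)^2)
  if (rss1 <= .Machine$double.eps * max(1, sum(values^2))) {
    warning("zero residual variance: degenerate fit")
    return(list(F = Inf, p = 0, df1 = 1, df2 = df2))
  }
  tab <- stats::anova(fit0, fit1)
  list(F = tab$F[2], p = tab$`Pr(>F)`[2], df1 = tab$Df[2], df2 = df2)
}
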