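#' Permutation inference with family-wise error control
#'
#' Freedman-Lane permutation of the vertexwise group GLM: the outcomes are
#' first fitted under the reduced (covariates-only) model; each permutation
#' shuffles the reduced-model residual rows, rebuilds surrogate outcomes
#' (reduced fit + permuted residuals), refits the full model and recomputes
#' the statistic map — the two-tailed absolute t, optionally TFCE-enhanced.
#' The maximum statistic over vertices in each permutation forms the null,
#' and each vertex's family-wise error rate is the add-one tail proportion
#' `p_FWER = (1 + #{max-null >= observed}) / (1 + n_perm)`, masked at
#' `alpha`.
#'
#' @param Y outcomes matrix, subjects x vertices (e.g. [vertex_totals()]
#'   stacked across subjects).
#' @param design a [glm_design()].
#' @param n_perm number of permutations. Fewer than 19 cannot reach
#'   p = 0.05 and triggers a warning.
#' @param rng_seed integer seed for the permutation draws.
#' @param use_tfce enhance each t-map with [tfce_enhance()] before taking
#'   the maximum (requires `mesh`).
#' @param mesh surface mesh for TFCE adjacency (ignored otherwise).
#' @param alpha significance level for the mask (default 0.05).
#' @param H,E,dh TFCE parameters; `dh` defaults to `max(|t_observed|)/100`
#'   and the same step is reused for every permutation so observed and null
#'   statistics are on the same scale.
#' @return A [stat_map()] with `statistic` = observed (enhanced) signed
#'   statistic, `p` = p_FWER, `mask`, plus `t_observed` and the
#'   `null_max` vector.
#' @export
permutation_fwer <- function(Y, design, n_perm = 1000, rng_seed = 1,
                             use_tfce = FALSE, mesh = NULL, alpha = 0.05,
                             H = 2, E = 0.5, dh = NULL) {
  Y <- as.matrix(Y)
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (n_perm < 19)
    warning("n_perm = ", n_perm, " cannot reach p = 0.05 (minimum add-one ",
            "p is ", signif(1 / (1 + n_perm), 3), ")")
  if (use_tfce && is.null(mesh))
    stop("use_tfce = TRUE requires a mesh")
  x <- design$X
  if (nrow(Y) != nrow(x)) stop("Y rows must match design rows")

  observed_t <- glm_tmap(Y, design)
  stat_of <- function(tvec) {
    if (use_tfce) tfce_enhance(tvec, mesh, H = H, E = E, dh = dh)
    else tvec
  }
  if (use_tfce && is.null(dh)) {
    mx <- max(abs(observed_t$statistic))
    dh <- if (mx > 0) mx / 100 else 1
  }
  obs_stat <- stat_of(observed_t$statistic)

  reduced <- x[, -design$group_col, drop = FALSE]
  qz <- qr(reduced)
  fitted_z <- qr.fitted(qz, Y)
  resid_z <- qr.resid(qz, Y)

  set.seed(rng_seed)
  null_max <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    perm <- sample.int(nrow(Y))
    y_star <- fitted_z + resid_z[perm, , drop = FALSE]
    t_star <- suppressWarnings(glm_tmap(y_star, design)$statistic)
    null_max[b] <- max(abs(stat_of(t_star)))
  }
  p_fwer <- (1 + colSums(outer(null_max, abs(obs_stat), ">="))) /
    (1 + n_perm)
  out <- stat_map(statistic = obs_stat, p = p_fwer,
                  mask = p_fwer < alpha, domain = "cortex",
                  threshold = alpha)
  out$t_observed <- observed_t$statistic
  out$null_max <- null_max
  out$n_perm <- n_perm
  out
}
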