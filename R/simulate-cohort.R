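#' Simulate a cohort of connectomes with planted gradients
#'
#' Generates one seed-by-vertex connectivity matrix per subject from the
#' generative model
#' \deqn{M_i = B + U W V^T + E_i,}
#' where `U`, `W`, `V` are the planted scores, component weights and
#' loadings, `B` is a constant baseline chosen so the noise-free matrix is
#' exactly non-negative, and `E_i` is i.i.d. Gaussian noise whose standard
#' deviation is linearly interpolated between the planted structure's
#' `noise_sd_at_min_age` (youngest scan) and `noise_sd_at_max_age` (oldest
#' scan) by the subject's scan age. Negative entries are clipped to zero,
#' since connectivity is a non-negative sum of streamline weights. Preterm
#' subjects additionally receive fixed vertexwise connectivity offsets
#' (added to every seed's row at the flagged vertices, before clipping).
#'
#' Phenotypes include scan age (uniform over `age_range`), birth age (term
#' subjects 37-42 weeks, preterm 24-36 weeks, never after scan age), sex
#' (balanced), group, and an `in_template` flag marking the `n_template`
#' oldest term-born subjects.
#'
#' @param planted a [plant_structure()] object.
#' @param n_subjects number of subjects (>= 4).
#' @param age_range scan-age range in weeks, e.g. `c(29, 45)`.
#' @param preterm_fraction fraction of subjects born preterm, in \[0, 1\].
#' @param preterm_effect numeric vector of per-vertex connectivity offsets
#'   (length = cortical vertex count, 0 for unaffected vertices), or `NULL`.
#' @param rng_seed integer seed; the cohort is bit-reproducible from it.
#' @param n_template how many of the oldest term subjects to flag as
#'   template members.
#' @return An object of class `synthetic_cohort`: `matrices` (list of
#'   [connectivity_matrix()] in state `"smoothed"`), `phenotypes`
#'   (data.frame), `planted`, and `rng_seed`.
#' @export
simulate_cohort <- function(planted, n_subjects = 50, age_range = c(29, 45),
                            preterm_fraction = 0, preterm_effect = NULL,
                            rng_seed = 1, n_template = 20) {
  stopifnot(inherits(planted, "planted_structure"))
  if (n_subjects < 4) stop("n_subjects must be at least 4")
  if (length(age_range) != 2 || diff(age_range) <= 0)
    stop("age_range must be an increasing pair of weeks")
  if (preterm_fraction < 0 || preterm_fraction > 1)
    stop("preterm_fraction must be in [0, 1]")
  n <- nrow(planted$true_scores)
  m <- nrow(planted$true_loadings)
  if (!is.null(preterm_effect) && length(preterm_effect) != m)
    stop("preterm_effect must have one offset per cortical vertex (", m, ")")

  signal <- planted$true_scores %*%
    (planted$component_weights * t(planted$true_loadings))
  baseline <- -min(signal)
  noise_free <- signal + baseline

  set.seed(rng_seed)
  scan_age <- stats::runif(n_subjects, age_range[1], age_range[2])
  n_preterm <- round(preterm_fraction * n_subjects)
  group <- rep("term", n_subjects)
  if (n_preterm > 0)
    group[sample.int(n_subjects, n_preterm)] <- "preterm"
  birth_draw <- ifelse(group == "preterm",
                       stats::runif(n_subjects, 24, 36),
                       stats::runif(n_subjects, 37, 42))
  birth_age <- pmin(birth_draw, scan_age - 0.5)
  sex <- rep_len(c("female", "male"), n_subjects)

  term_idx <- which(group == "term")
  in_template <- rep(FALSE, n_subjects)
  if (length(term_idx) > 0) {
    oldest <- term_idx[order(scan_age[term_idx],
                             decreasing = TRUE)][seq_len(min(n_template,
                                                             length(term_idx)))]
    in_template[oldest] <- TRUE
  }

  frac <- (scan_age - age_range[1]) / diff(age_range)
  noise_sd <- planted$noise_sd_at_min_age +
    frac * (planted$noise_sd_at_max_age - planted$noise_sd_at_min_age)

  matrices <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    vals <- noise_free
    if (noise_sd[i] > 0)
      vals <- vals + matrix(stats::rnorm(n * m, sd = noise_sd[i]), n, m)
    if (group[i] == "preterm" && !is.null(preterm_effect))
      vals <- vals + rep(preterm_effect, each = n)
    matrices[[i]] <- connectivity_matrix(
      pmax(vals, 0),
      vertex_ids = planted$cortex_vertices - 1L,
      state = "smoothed")
  }

  phenotypes <- data.frame(
    subject_id = sprintf("sub-%03d", seq_len(n_subjects)),
    scan_age_weeks = scan_age,
    birth_age_weeks = birth_age,
    sex = sex,
    group = group,
    in_template = in_template,
    stringsAsFactors = FALSE)

  structure(list(matrices = matrices, phenotypes = phenotypes,
                 planted = planted, rng_seed = rng_seed),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  ph <- x$phenotypes
  cat(sprintf(
    "<synthetic_cohort> %d subjects (%d preterm), scan age %.1f-%.1f weeks\n",
    nrow(ph), sum(ph$group == "preterm"), min(ph$scan_age_weeks),
    max(ph$scan_age_weeks)))
  cat(sprintf("  matrices: %d seeds x %d vertices, k = %d planted components\n",
              nrow(x$matrices[[1]]$values), ncol(x$matrices[[1]]$values),
              x$planted$k))
  invisible(x)
}

#' Noise-free cohort matrix implied by a planted structure
#'
#' The baseline-shifted rank-k matrix every subject's connectome fluctuates
#' around; useful as the ground-truth reference in round-trip tests.
#'
#' @param planted a [plant_structure()] object.
#' @return A `connectivity_matrix` in state `"smoothed"`.
#' @export
noise_free_matrix <- function(planted) {
  stopifnot(inherits(planted, "planted_structure"))
  signal <- planted$true_scores %*%
    (planted$component_weights * t(planted$true_loadings))
  connectivity_matrix(signal - min(signal),
                      vertex_ids = planted$cortex_vertices - 1L,
                      state = "smoothed")
}
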