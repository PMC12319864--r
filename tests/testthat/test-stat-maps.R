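test_that("BH adjustment on a hand-worked example", {
  res <- fdr_bh(c(0.001, 0.4, 0.9), q = 0.05)
  # step-up: p_(1)=0.001 <= 0.05/3 -> reject only the first
  expect_identical(res$mask, c(TRUE, FALSE, FALSE))
  expect_equal(res$p_adjusted, c(0.003, 0.6, 0.9), tolerance = 1e-12)
})

test_that("no rejections when every p is 1; empty input gives empty output", {
  expect_false(any(fdr_bh(rep(1, 10))$mask))
  res <- fdr_bh(numeric(0))
  expect_length(res$p_adjusted, 0)
  expect_length(res$mask, 0)
})

test_that("BH matches the brute-force step-up rule on random vectors", {
  set.seed(12)
  brute_bh <- function(p, q) {
    m <- length(p)
    srt <- sort(p)
    ok <- which(srt <= q * seq_len(m) / m)
    if (length(ok) == 0) return(rep(FALSE, m))
    p <= srt[max(ok)]
  }
  for (rep in 1:200) {
    m <- sample(1:40, 1)
    p <- runif(m)^sample(c(1, 2, 4), 1)  # mix of null-ish and signal-ish
    q <- runif(1, 0.01, 0.2)
    expect_identical(fdr_bh(p, q)$mask, brute_bh(p, q))
  }
})

test_that("NA p-values stay outside the FDR family", {
  res <- fdr_bh(c(0.01, NA, 0.02), q = 0.05)
  expect_true(is.na(res$p_adjusted[2]))
  expect_false(res$mask[2])
  expect_equal(res$p_adjusted[c(1, 3)],
               p.adjust(c(0.01, 0.02), "BH"))
})

make_aligned_cohort <- function(noise_min = 0.4, noise_max = 0.1, n = 20,
                                seed = 15, preterm_fraction = 0,
                                preterm_effect = NULL) {
  pl <- tg_planted(noise_min = noise_min, noise_max = noise_max)
  co <- simulate_cohort(pl, n_subjects = n, rng_seed = seed,
                        preterm_fraction = preterm_fraction,
                        preterm_effect = preterm_effect)
  tm <- build_template(co$matrices, co$phenotypes, n_template = 4, k = 5)
  aligned <- lapply(co$matrices, function(m)
    procrustes_align(decompose_matrix(m, 5), tm$decomposition, 5))
  list(cohort = co, template = tm, aligned = aligned)
}

test_that("perfect age dependence gives r = 1 at every seed", {
  fix <- make_aligned_cohort(n = 10)
  ages <- fix$cohort$phenotypes$scan_age_weeks
  # overwrite aligned scores with an exact linear function of age
  fake <- lapply(seq_along(fix$aligned), function(i) {
    a <- fix$aligned[[i]]
    a$aligned_scores[, 1] <- 2 * ages[i] + seq_len(nrow(a$aligned_scores))
    a
  })
  sm <- age_correlation_map(fake, ages, component = 1, domain = "scores")
  expect_equal(sm$statistic, rep(1, length(sm$statistic)), tolerance = 1e-9)
  expect_true(all(sm$mask))
  expect_equal(sm$domain, "thalamus")
})

test_that("elements constant across subjects are excluded from the family", {
  fix <- make_aligned_cohort(n = 8)
  ages <- fix$cohort$phenotypes$scan_age_weeks
  fake <- lapply(fix$aligned, function(a) {
    a$aligned_scores[, 1] <- seq_len(nrow(a$aligned_scores))
    a$aligned_scores[2, 1] <- 99  # still constant across subjects
    a
  })
  sm <- age_correlation_map(fake, ages, 1, "scores")
  expect_true(all(is.na(sm$statistic)))
  expect_false(any(sm$mask))
})

test_that("under permuted ages the FDR discovery proportion is controlled", {
  fix <- make_aligned_cohort(n = 20, seed = 44)
  ages <- fix$cohort$phenotypes$scan_age_weeks
  set.seed(5)
  props <- replicate(60, {
    sm <- age_correlation_map(fix$aligned, sample(ages), 1, "loadings")
    mean(sm$mask)
  })
  expect_lte(mean(props), 0.05)
})

test_that("axis correlations recover planted geometry", {
  grid <- tg_grid()
  # values equal to the y coordinate correlate perfectly on y
  res <- axis_correlation(grid$coordinates[, 2], grid, "y")
  expect_equal(res$r, 1, tolerance = 1e-12)
  # residualizing against all axes kills all three correlations
  set.seed(19)
  v <- rnorm(nrow(grid$coordinates))
  v <- resid(lm(v ~ grid$coordinates))
  for (ax in c("x", "y", "z"))
    expect_lt(abs(axis_correlation(v, grid, ax)$r), 0.05)
  # planted component 1 is built from the x and y axes
  pl <- tg_planted(k = 1)
  for (ax in c("x", "y"))
    expect_gte(abs(axis_correlation(pl$true_scores[, 1], grid, ax)$r), 0.5)
})

test_that("vertex totals equal brute-force column sums", {
  m <- connectivity_matrix(matrix(1, 3, 4), state = "smoothed")
  expect_equal(vertex_totals(m), rep(3, 4))
  single <- connectivity_matrix(rbind(c(1, 0, 2.5)), state = "filtered")
  expect_equal(vertex_totals(single), c(1, 0, 2.5))
  set.seed(3)
  vals <- matrix(rexp(6 * 11), 6, 11)
  r <- connectivity_matrix(vals, state = "smoothed")
  expect_equal(vertex_totals(r),
               vapply(1:11, function(j) sum(vals[, j]), numeric(1)))
  expect_equal(sum(vertex_totals(r, proportion = TRUE)), 1)
  norm <- normalize_sigmoid(r)$matrix
  expect_error(vertex_totals(norm), "before normalization")
})
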