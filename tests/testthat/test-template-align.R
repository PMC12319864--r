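zero_noise_cohort <- function(n = 6, k = 3, seed = 2) {
  pl <- tg_planted(noise_min = 0, noise_max = 0, k = k)
  simulate_cohort(pl, n_subjects = n, rng_seed = seed)
}

test_that("a single-subject template equals that subject's decomposition", {
  co <- zero_noise_cohort()
  tm <- build_template(co$matrices, co$phenotypes, n_template = 1, k = 3)
  oldest <- which.max(co$phenotypes$scan_age_weeks)
  d <- decompose_matrix(co$matrices[[oldest]], 3)
  expect_equal(tm$decomposition$scores, d$scores, tolerance = 1e-10)
  expect_equal(tm$decomposition$loadings, d$loadings, tolerance = 1e-10)
  expect_identical(tm$subject_ids, co$phenotypes$subject_id[oldest])
})

test_that("identical input matrices average to any one of them", {
  co <- zero_noise_cohort()
  tm <- build_template(co$matrices, co$phenotypes, n_template = 4, k = 2)
  expect_equal(tm$mean_matrix$values, co$matrices[[1]]$values,
               tolerance = 1e-12)
})

test_that("zero-noise template recovers the planted loadings exactly", {
  co <- zero_noise_cohort(k = 3)
  tm <- build_template(co$matrices, co$phenotypes, n_template = 4, k = 3)
  for (j in 1:3)
    expect_gte(abs(cor(tm$decomposition$loadings[, j],
                       co$planted$true_loadings[, j])), 0.999)
})

test_that("template selection takes the oldest eligible term subjects", {
  pl <- tg_planted()
  co <- simulate_cohort(pl, n_subjects = 12, preterm_fraction = 0.25,
                        rng_seed = 10)
  ph <- co$phenotypes
  tm <- build_template(co$matrices, ph, n_template = 3, k = 2)
  term <- ph[ph$group == "term", ]
  expected <- term$subject_id[order(term$scan_age_weeks,
                                    decreasing = TRUE)][1:3]
  expect_identical(tm$subject_ids, expected)
  # leave-one-out: excluded subject never appears
  loo <- build_template(co$matrices, ph, n_template = 3, k = 2,
                        exclude = expected[1])
  expect_false(expected[1] %in% loo$subject_ids)
  expect_error(build_template(co$matrices, ph, n_template = 10, k = 2),
               "eligible")
})

test_that("aligning a decomposition to itself is the identity", {
  co <- zero_noise_cohort()
  d <- decompose_matrix(co$matrices[[1]], 5)
  al <- procrustes_align(d, d, k_align = 3)
  expect_equal(al$rotation, diag(3), tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(al$aligned_scores, d$scores[, 1:3], tolerance = 1e-8)
})

test_that("column swaps and sign flips are undone by alignment", {
  co <- zero_noise_cohort()
  d <- decompose_matrix(co$matrices[[1]], 3)
  perm <- d
  perm$scores <- d$scores[, c(2, 1, 3)]
  perm$scores[, 1] <- -perm$scores[, 1]
  perm$loadings <- d$loadings[, c(2, 1, 3)]
  perm$loadings[, 1] <- -perm$loadings[, 1]
  al <- procrustes_align(perm, d, k_align = 3)
  expect_equal(al$aligned_scores, d$scores[, 1:3], tolerance = 1e-8)
  expect_equal(al$aligned_loadings, d$loadings[, 1:3], tolerance = 1e-8)
})

test_that("a planted rotation is recovered as its transpose", {
  co <- simulate_cohort(tg_planted(), n_subjects = 5, rng_seed = 77)
  d <- decompose_matrix(co$matrices[[1]], 5)  # noise makes all 5 ranks live
  set.seed(31)
  for (rep in 1:10) {
    r0 <- random_orthogonal(5)
    rotated <- d
    rotated$scores <- d$scores %*% r0
    rotated$loadings <- d$loadings %*% r0
    al <- procrustes_align(rotated, d, k_align = 5)
    expect_equal(al$rotation, t(r0), tolerance = 1e-8)
    expect_equal(al$aligned_scores, d$scores, tolerance = 1e-8)
  }
})

test_that("rotation is orthogonal and preserves subspace energy", {
  pl <- tg_planted()
  co <- simulate_cohort(pl, n_subjects = 6, rng_seed = 12)
  tm <- build_template(co$matrices, co$phenotypes, n_template = 4, k = 5)
  d <- decompose_matrix(co$matrices[[1]], 5)
  al <- procrustes_align(d, tm$decomposition, k_align = 5)
  expect_equal(crossprod(al$rotation), diag(5), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(norm(al$aligned_scores, "F"), norm(d$scores[, 1:5], "F"),
               tolerance = 1e-8)
  # optimality: alignment never increases the distance to the template
  before <- norm(d$scores[, 1:5] - tm$decomposition$scores[, 1:5], "F")
  after <- norm(al$aligned_scores - tm$decomposition$scores[, 1:5], "F")
  expect_lte(after, before + 1e-10)
})

test_that("similarity to template behaves at the extremes", {
  co <- zero_noise_cohort()
  tm <- build_template(co$matrices, co$phenotypes, n_template = 4, k = 5)
  d <- decompose_matrix(co$matrices[[2]], 5)
  al <- procrustes_align(d, tm$decomposition, k_align = 3)
  expect_equal(similarity_to_template(al, tm$decomposition, 1, "scores"), 1,
               tolerance = 1e-6)
  flipped <- al
  flipped$aligned_scores <- -al$aligned_scores
  expect_equal(similarity_to_template(flipped, tm$decomposition, 1,
                                      "scores"), -1, tolerance = 1e-6)
  broken <- al
  broken$aligned_loadings[, 2] <- 0
  expect_warning(
    r <- similarity_to_template(broken, tm$decomposition, 2, "loadings"),
    "constant")
  expect_true(is.na(r))
  expect_error(similarity_to_template(al, tm$decomposition, 4, "scores"),
               "k_align")
})

test_that("seed-count mismatches cannot be aligned", {
  co <- zero_noise_cohort()
  d <- decompose_matrix(co$matrices[[1]], 3)
  small <- decompose_matrix(subset_seeds(co$matrices[[2]], 1:100), 3)
  expect_error(procrustes_align(small, d, k_align = 3), "differ")
  expect_error(procrustes_align(d, d, k_align = 9), "k_align")
})
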