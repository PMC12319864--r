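fake_phenotypes <- function(n, seed = 1, preterm_fraction = 0.5) {
  set.seed(seed)
  data.frame(group = rep(c("preterm", "term"),
                         c(round(n * preterm_fraction),
                           n - round(n * preterm_fraction))),
             scan_age_weeks = runif(n, 37, 45),
             sex = rep_len(c("female", "male"), n))
}

test_that("with no covariates the GLM t equals the pooled two-sample t", {
  set.seed(21)
  n <- 16
  g <- rep(c(1, 0), each = n / 2)
  y <- matrix(rnorm(n * 12), n, 12)
  design <- list(X = cbind(1, g), contrast = c(0, 1), group_col = 2L)
  tm <- glm_tmap(y, design)
  for (j in 1:12) {
    tt <- t.test(y[g == 1, j], y[g == 0, j], var.equal = TRUE)
    expect_equal(tm$statistic[j], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(tm$p[j], tt$p.value, tolerance = 1e-10)
  }
})

test_that("an exact group effect with zero noise is flagged as degenerate", {
  ph <- fake_phenotypes(10)
  design <- glm_design(ph)
  y <- matrix(design$X[, 2] * 3, 10, 2)
  expect_warning(tm <- glm_tmap(y, design), "degenerate")
  expect_true(all(is.infinite(tm$statistic)))
})

test_that("covariate-only fits ignore group labels entirely", {
  ph <- fake_phenotypes(14, seed = 3)
  set.seed(4)
  y <- matrix(rnorm(14 * 5), 14, 5)
  x_red <- glm_design(ph)$X[, -2]
  fit1 <- qr.resid(qr(x_red), y)
  ph2 <- ph
  ph2$group <- sample(ph$group)  # permuted labels
  x_red2 <- glm_design(ph2)$X[, -2]
  expect_equal(qr.resid(qr(x_red2), y), fit1, tolerance = 1e-12)
})

test_that("the design matrix is validated", {
  ph <- fake_phenotypes(8)
  expect_s3_class(glm_design(ph), "glm_design")
  ph$sex <- "female"  # constant column -> collinear with intercept
  expect_error(glm_design(ph), "rank deficient")
  expect_error(glm_design(data.frame(a = 1)), "columns")
})

test_that("ancova F vanishes for group-orthogonal values", {
  ph <- fake_phenotypes(24, seed = 6)
  design <- glm_design(ph)
  set.seed(7)
  v <- rnorm(24)
  # project out the group effect (within the covariate model)
  full_res <- qr.resid(qr(design$X), v)
  reduced_fit <- v - qr.resid(qr(design$X[, -2]), v)
  v_orth <- full_res + reduced_fit
  res <- group_scalar_ancova(v_orth, design)
  expect_lt(res$F, 1e-16)
  expect_equal(res$p, 1, tolerance = 1e-8)
})

test_that("ancova F equals the brute-force RSS-difference formula", {
  ph <- fake_phenotypes(30, seed = 8)
  design <- glm_design(ph)
  set.seed(9)
  v <- rnorm(30) + 0.8 * (ph$group == "preterm")
  res <- group_scalar_ancova(v, design)
  # independent oracle: explicit projections
  rss <- function(m) sum(qr.resid(qr(m), v)^2)
  rss0 <- rss(design$X[, -2])
  rss1 <- rss(design$X)
  f <- (rss0 - rss1) / (rss1 / (30 - 4))
  expect_equal(res$F, f, tolerance = 1e-10)
  expect_equal(res$p, pf(f, 1, 26, lower.tail = FALSE), tolerance = 1e-10)
  expect_equal(res$df2, 26)
})

test_that("a perfectly separating scalar triggers the degenerate warning", {
  ph <- fake_phenotypes(12, seed = 10)
  design <- glm_design(ph)
  expect_warning(res <- group_scalar_ancova(as.numeric(ph$group == "preterm"),
                                            design), "degenerate")
  expect_equal(res$p, 0)
})

test_that("empirical ancova power matches the noncentral-F prediction", {
  n <- 100
  delta <- 0.6
  ph <- fake_phenotypes(n, seed = 11)
  design <- glm_design(ph)
  g <- design$X[, 2]
  # noncentrality of the partial F: delta^2 * ||M_z g||^2 / sigma^2
  gz <- qr.resid(qr(design$X[, -2]), g)
  ncp <- delta^2 * sum(gz^2)
  df2 <- n - 4
  predicted <- pf(qf(0.95, 1, df2), 1, df2, ncp = ncp, lower.tail = FALSE)
  set.seed(12)
  rejections <- replicate(500, {
    v <- delta * g + rnorm(n)
    group_scalar_ancova(v, design)$p < 0.05
  })
  expect_lt(abs(mean(rejections) - predicted), 0.05)
})
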