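toy_matrix <- function(vals, state = "smoothed") {
  connectivity_matrix(vals, state = state)
}

test_that("the <100-connected-vertex rule removes 99 and keeps 100", {
  set.seed(1)
  make_row <- function(nnz, m = 300) {
    r <- numeric(m)
    r[sample.int(m, nnz)] <- runif(nnz)
    r
  }
  m <- toy_matrix(rbind(make_row(99), make_row(100), make_row(150)))
  expect_message(kept <- filter_seeds(m, 100), "1 of 3 seeds removed")
  expect_identical(kept, c(2L, 3L))
})

test_that("a toy nonzero-count pattern retains exactly the right seeds", {
  set.seed(2)
  counts <- c(150, 100, 99, 0, 300)
  vals <- t(vapply(counts, function(nnz) {
    r <- numeric(400)
    if (nnz > 0) r[sample.int(400, nnz)] <- runif(nnz)
    r
  }, numeric(400)))
  kept <- suppressMessages(filter_seeds(toy_matrix(vals), 100))
  expect_identical(kept, c(1L, 2L, 5L))  # 0-based {0, 1, 4}
})

test_that("all-positive matrices retain every seed; empty retention errors", {
  m <- toy_matrix(matrix(1, 4, 150))
  expect_identical(suppressMessages(filter_seeds(m, 100)), 1:4)
  expect_error(suppressMessages(filter_seeds(m, 151)), "threshold")
})

test_that("filtering agrees with brute-force nonzero counts", {
  set.seed(33)
  for (rep in 1:20) {
    vals <- matrix(rbinom(30 * 80, 1, 0.4) * runif(30 * 80), 30, 80)
    thr <- sample(10:30, 1)
    kept <- suppressMessages(filter_seeds(toy_matrix(vals), thr))
    brute <- which(vapply(seq_len(30),
                          function(i) sum(vals[i, ] != 0) >= thr,
                          logical(1)))
    expect_identical(kept, brute)
  }
})

test_that("sigmoid value at the column mean is 0.5 before rescaling", {
  x <- c(1, 2, 3, 6)
  m <- toy_matrix(cbind(x))
  mu <- mean(x)
  sd_pop <- sqrt(mean((x - mu)^2))
  s_raw <- 1 / (1 + exp(-(x - mu) / sd_pop))
  res <- normalize_sigmoid(m)
  # reconstruct the pre-rescale value at an artificial mean input
  expect_equal(1 / (1 + exp(-(mu - mu) / sd_pop)), 0.5)
  expect_equal(res$params$mean, mu, ignore_attr = TRUE)
  expect_equal(res$params$sd, sd_pop, ignore_attr = TRUE)
  expect_equal(res$matrix$values[, 1],
               (s_raw - min(s_raw)) / (max(s_raw) - min(s_raw)),
               tolerance = 1e-12)
})

test_that("the (0, 1, 2) column maps to (0, 0.5, 1)", {
  m <- toy_matrix(cbind(c(0, 1, 2)))
  res <- normalize_sigmoid(m)
  sigma <- sqrt(2 / 3)
  s <- c(1 / (1 + exp(1 / sigma)), 0.5, 1 / (1 + exp(-1 / sigma)))
  expect_equal(res$params$sd, sigma, ignore_attr = TRUE)
  expect_equal(res$params$min, s[1], ignore_attr = TRUE)
  expect_equal(res$params$max, s[3], ignore_attr = TRUE)
  expect_equal(res$matrix$values[, 1], c(0, 0.5, 1), tolerance = 1e-12)
})

test_that("normalization is columnwise monotone with exact [0, 1] range", {
  set.seed(9)
  vals <- matrix(rexp(40 * 25), 40, 25)
  res <- normalize_sigmoid(toy_matrix(vals))
  out <- res$matrix$values
  expect_equal(apply(out, 2, min), rep(0, 25), tolerance = 1e-12)
  expect_equal(apply(out, 2, max), rep(1, 25), tolerance = 1e-12)
  for (j in sample(25, 8))
    expect_true(all(diff(out[order(vals[, j]), j]) >= -1e-12))
  expect_equal(res$matrix$state, "normalized")
})

test_that("constant columns become the constant 0.5", {
  vals <- cbind(c(1, 1, 1), c(0, 1, 5))
  out <- normalize_sigmoid(toy_matrix(vals))$matrix$values
  expect_equal(out[, 1], rep(0.5, 3))
})

test_that("normalization preconditions", {
  expect_error(normalize_sigmoid(toy_matrix(matrix(1, 1, 4))), "2 seeds")
  raw <- toy_matrix(matrix(1, 3, 4), state = "raw")
  expect_error(normalize_sigmoid(raw), "smoothed or filtered")
})
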