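test_that("thresholds match normal quantiles of cumulative proportions", {
  # 50/50 binary split: single threshold at 0
  expect_equal(estimate_thresholds(rep(1:2, 50)), 0)
  # exact quartile counts: qnorm(0.25, 0.50, 0.75)
  x <- rep(1:4, each = 25)
  expect_equal(estimate_thresholds(x), stats::qnorm(c(0.25, 0.5, 0.75)),
               tolerance = 1e-12)
})

test_that("degenerate and empty-category columns follow the configured policy", {
  expect_error(estimate_thresholds(rep(3, 40), n_categories = 4,
                                   empty = "error"))
  # merge policy collapses the empty category; thresholds stay increasing
  tau <- estimate_thresholds(rep(c(1, 2, 4), c(10, 20, 10)),
                             n_categories = 4, empty = "merge")
  expect_true(all(diff(tau) > 0))
  # a single-category column cannot be correlated with anything
  expect_error(polychoric_pair(rep(2, 50), rep(1:2, 25)))
})

test_that("independent columns give near-zero polychoric correlation", {
  set.seed(4)
  x <- sample(1:4, 5000, replace = TRUE)
  y <- sample(1:4, 5000, replace = TRUE)
  expect_lt(abs(polychoric_pair(x, y)$rho), 0.05)
})

test_that("tetrachoric estimate recovers rho = 0.5 via the quadrant identity", {
  # closed-form quadrant probabilities at rho = 0.5:
  # P(both above median) = 1/4 + asin(0.5) / (2 pi)
  p11 <- 0.25 + asin(0.5) / (2 * pi)
  n <- 20000
  # build a sample whose 2x2 table matches the exact cell probabilities
  n11 <- round(n * p11); n10 <- round(n * (0.5 - p11))
  n01 <- n10; n00 <- n - n11 - n10 - n01
  x <- rep(c(2, 2, 1, 1), c(n11, n10, n01, n00))
  y <- rep(c(2, 1, 2, 1), c(n11, n10, n01, n00))
  expect_lt(abs(polychoric_pair(x, y)$rho - 0.5), 0.01)
  # and from actual bivariate-normal draws
  set.seed(7)
  f <- stats::rnorm(n)
  u <- 0.5 * f + sqrt(1 - 0.25) * stats::rnorm(n)
  est <- polychoric_pair((f > 0) + 1, (u > 0) + 1)
  expect_lt(abs(est$rho - 0.5), 0.02)
  expect_true(est$converged)
})

test_that("four-category polychoric is consistent at rho = 0.7", {
  set.seed(12)
  n <- 20000
  f <- stats::rnorm(n)
  u <- 0.7 * f + sqrt(1 - 0.49) * stats::rnorm(n)
  tau <- stats::qnorm(c(0.25, 0.5, 0.75))
  x <- discretize(cbind(f), list(tau))
  y <- discretize(cbind(u), list(tau))
  expect_lt(abs(polychoric_pair(x[, 1], y[, 1])$rho - 0.7), 0.02)
})

test_that("matrix assembly is consistent with the pairwise estimator", {
  sim <- generate_responses(generator_spec(seed = 13), n = 300)
  pc <- polychoric(sim$responses)
  expect_equal(pc$matrix[2, 1],
               polychoric_pair(sim$responses[, 1], sim$responses[, 2])$rho,
               tolerance = 1e-10)
  expect_identical(pc$matrix, t(pc$matrix))
  expect_equal(unname(diag(pc$matrix)), rep(1, 10))
})

test_that("one-factor data reproduces the lambda-lambda-transpose oracle", {
  X <- sim_one_factor(20000, p = 6, lambda = 0.8, seed = 19)
  pc <- polychoric(X)
  off <- pc$matrix[lower.tri(pc$matrix)]
  expect_lt(max(abs(off - 0.64)), 0.025)
})

test_that("PSD repair clips negative eigenvalues and preserves unit diagonal", {
  R <- diag(3)
  R[1, 2] <- R[2, 1] <- 0.9
  R[1, 3] <- R[3, 1] <- 0.9
  R[2, 3] <- R[3, 2] <- -0.5   # indefinite
  expect_lt(min(eigen(R, symmetric = TRUE)$values), 0)
  repair <- wordfx:::psd_smooth(R)
  expect_true(repair$smoothed)
  Rs <- repair$matrix
  expect_gte(min(eigen(Rs, symmetric = TRUE)$values), 0)
  expect_equal(unname(diag(Rs)), rep(1, 3))
  expect_identical(Rs, t(Rs))
})

test_that("correlation matrices round-trip through the CSV fixture format", {
  pc <- polychoric(generate_responses(generator_spec(seed = 6),
                                      n = 200)$responses)
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f), add = TRUE)
  write_corr_csv(pc$matrix, f)
  back <- read_corr_csv(f)
  expect_equal(back, pc$matrix, tolerance = 1e-12)
})

test_that("packaged Table-style fixtures are valid correlation matrices", {
  for (s in c("total", "steinmann", "arias")) {
    d <- rses_polychoric(s)
    expect_identical(dim(d$matrix), c(10L, 10L))
    expect_identical(d$matrix, t(d$matrix))
    expect_equal(unname(diag(d$matrix)), rep(1, 10))
    expect_gt(min(eigen(d$matrix, symmetric = TRUE)$values), 0)
  }
  expect_identical(rses_polychoric("total")$n, 632L)
  expect_identical(rses_polychoric("steinmann")$n, 588L)
  expect_identical(rses_polychoric("arias")$n, 582L)
})

test_that("pbvn matches the product rule and mvtnorm at extreme correlation", {
  expect_equal(pbvn(0.3, -0.2, 0), stats::pnorm(0.3) * stats::pnorm(-0.2),
               tolerance = 1e-12)
  expect_equal(pbvn(0.5, 1.2, 1), stats::pnorm(pmin(0.5, 1.2)),
               tolerance = 1e-7)
  expect_equal(pbvn(0, 0, 0.5), 0.25 + asin(0.5) / (2 * pi),
               tolerance = 1e-10)
  if (requireNamespace("mvtnorm", quietly = TRUE)) {
    expect_equal(pbvn(0.4, -0.7, 0.98),
                 mvtnorm::pmvnorm(upper = c(0.4, -0.7),
                                  corr = matrix(c(1, 0.98, 0.98, 1), 2))[1],
                 tolerance = 1e-7)
  }
})
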