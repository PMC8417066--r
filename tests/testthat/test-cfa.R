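test_that("degrees of freedom match the published model table", {
  pol <- rses_polarity()
  expect_identical(cfa_spec("one_factor", pol)$df, 35)
  expect_identical(cfa_spec("two_factor", pol)$df, 34)
  expect_identical(cfa_spec("riifa", pol)$df, 34)
  expect_identical(cfa_spec("one_factor", pol, c("p4", "p5"))$df, 34)
  expect_identical(cfa_spec("two_factor", pol, c("p4", "p5"))$df, 33)
  expect_identical(cfa_spec("riifa", pol, c("p4", "p5"))$df, 33)
  expect_error(cfa_spec("riifa", rep("positive", 10)),
               "requires negatively worded items")
  expect_error(cfa_spec("one_factor", pol, c("p4", "zz")),
               "exactly two items")
})

test_that("one-factor self-consistency: exact recovery and zero discrepancy", {
  lambda <- seq(0.5, 0.9, length.out = 10)
  R <- onef_matrix(lambda)
  fit <- fit_cfa(R, 500, cfa_spec("one_factor", polarity_of(10)))
  expect_lt(max(abs(abs(fit$loadings) - lambda)), 1e-5)
  expect_lt(fit$discrepancy, 1e-10)
  expect_equal(fit$CFI, 1)
  expect_equal(fit$TLI, 1)
  expect_equal(fit$RMSEA, 0)
  expect_lt(fit$SRMR, 1e-6)
  expect_lt(max(abs(diag(fit$implied) - 1)), 1e-8)
  expect_lt(max(abs(fit$communalities - (fit$loadings^2))), 1e-8)
})

test_that("two-factor-theta self-consistency recovers phi and theta", {
  lambda <- c(0.7, 0.6, 0.8, 0.65, 0.75, 0.55, 0.6, 0.7, 0.5, 0.65)
  pol <- polarity_of(10)
  phi <- 0.8
  R <- tcrossprod(lambda)
  cross <- outer(pol == "positive", pol == "positive", "!=")
  R[cross] <- R[cross] * phi
  R[1, 2] <- R[2, 1] <- R[1, 2] + 0.15   # freed p1-p2 error covariance
  diag(R) <- 1
  fit <- fit_cfa(R, 500, cfa_spec("two_factor", pol, c("p1", "p2")))
  expect_lt(abs(fit$factor_correlation - phi), 1e-5)
  expect_lt(abs(fit$theta - 0.15), 1e-5)
  expect_lt(max(abs(abs(fit$loadings) - lambda)), 1e-5)
  expect_lt(fit$discrepancy, 1e-10)
})

test_that("riifa standardized method loadings share a single magnitude", {
  tot <- rses_polychoric("total")
  fit <- fit_cfa(tot$matrix, tot$n, cfa_spec("riifa", rses_polarity()))
  expect_length(fit$method_loading, 1)
  expect_equal(fit$method_loading, sqrt(fit$method_variance),
               tolerance = 1e-12)
  # implied pattern: the method factor contributes +v within polarity blocks
  # and -v across, identically for every pair
  est <- wordfx:::cfa_unpack(fit$spec, fit$par)
  base <- tcrossprod(fit$loadings)
  s <- ifelse(rses_polarity() == "positive", 1, -1)
  expect_equal(unname(fit$implied - est$v * tcrossprod(s))[2, 1],
               unname(base)[2, 1], tolerance = 1e-10)
})

test_that("index arithmetic matches hand-evaluated formulas", {
  idx <- wordfx:::index_arithmetic(chi = 100, df = 35, chib = 1000, dfb = 45,
                                   n = 632, srmr = 0.04)
  expect_equal(idx$CFI, 1 - 65 / 955, tolerance = 1e-12)     # 0.9319...
  expect_equal(idx$CFI, 0.932, tolerance = 5e-4)
  expect_equal(idx$RMSEA, sqrt(65 / (35 * 631)), tolerance = 1e-12)
  expect_lt(abs(idx$RMSEA - 0.0543), 1e-4)   # hand value ~0.05425
  expect_equal(idx$TLI, ((1000 / 45) - (100 / 35)) / ((1000 / 45) - 1),
               tolerance = 1e-12)
  expect_true(idx$RMSEA_lo <= idx$RMSEA && idx$RMSEA <= idx$RMSEA_hi)
  # saturated convention
  sat <- wordfx:::index_arithmetic(0, 0, 1000, 45, 632, 0)
  expect_identical(sat$CFI, 1)
  expect_identical(sat$RMSEA, 0)
})

test_that("nesting: the one-factor discrepancy dominates 2F and RIIFA", {
  pol <- rses_polarity()
  for (s in c("total", "steinmann", "arias")) {
    d <- rses_polychoric(s)
    f1 <- fit_cfa(d$matrix, d$n, cfa_spec("one_factor", pol))
    f2 <- fit_cfa(d$matrix, d$n, cfa_spec("two_factor", pol))
    fr <- fit_cfa(d$matrix, d$n, cfa_spec("riifa", pol))
    expect_gte(f1$discrepancy, f2$discrepancy - 1e-10)
    expect_gte(f1$discrepancy, fr$discrepancy - 1e-10)
  }
})

test_that("modification indices find a planted error correlation", {
  # five items so the freed pair is uniquely identified (in a 4-item
  # one-factor model, freeing the complementary pair fits equally well)
  lambda <- c(0.7, 0.6, 0.75, 0.65, 0.55)
  R <- onef_matrix(lambda, theta = 0.4 * sqrt((1 - 0.7^2) * (1 - 0.6^2)),
                   pair = c(1, 2))
  pol <- polarity_of(5, n_pos = 3)
  fit <- fit_cfa(R, 400, cfa_spec("one_factor", pol))
  mi <- modification_indices(fit)
  expect_identical(mi$parameter[1], "p1~~p2")
  expect_identical(mi$type[1], "errcov")
  expect_lt(abs(mi$sepc[1] - 0.4), 0.05)
  # MI within 15% of the actual chi-square improvement from refitting
  freed <- fit_cfa(R, 400, cfa_spec("one_factor", pol, c(1, 2)))
  drop <- fit$chi_square - freed$chi_square
  expect_lt(abs(mi$mi[1] - drop), 0.15 * drop)
  # an already-free parameter is excluded from the table
  mi2 <- modification_indices(freed)
  expect_false(any(mi2$parameter == "p1~~p2"))
  # table is sorted by decreasing MI
  expect_true(all(diff(mi$mi) <= 1e-8))
})

test_that("heywood communalities trigger a warning, not an error", {
  R <- matrix(c(1, 0.8, 0.8,
                0.8, 1, 0.4,
                0.8, 0.4, 1), 3, 3)
  # implied single-factor loading for item 1: sqrt(.8*.8/.4) > 1
  expect_warning(
    fit_cfa(R, 200, cfa_spec("one_factor", polarity_of(3, 2))),
    "Heywood")
})

test_that("input validation and estimator options", {
  pol <- rses_polarity()
  tot <- rses_polychoric("total")
  expect_error(fit_cfa(tot$matrix * 2, tot$n, cfa_spec("one_factor", pol)),
               "unit diagonal")
  expect_error(fit_cfa(tot$matrix, 5, cfa_spec("one_factor", pol)),
               "sample size")
  fu <- fit_cfa(tot$matrix, tot$n, cfa_spec("one_factor", pol),
                estimator = "uls")
  fd <- fit_cfa(tot$matrix, tot$n, cfa_spec("one_factor", pol))
  # estimators agree closely but not identically on real data
  expect_lt(max(abs(fu$loadings - fd$loadings)), 0.05)
  expect_false(identical(fu$loadings, fd$loadings))
  expect_output(print(fd), "Least-squares CFA")
})
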