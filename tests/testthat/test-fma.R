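test_that("free-parameter counts match the constraint enumeration", {
  pol <- rses_polarity()
  expect_identical(steinmann_spec(pol)$n_free, 38L)
  expect_identical(arias_spec(pol)$n_free, 23L)
  expect_error(steinmann_spec(rep("positive", 10)),
               "classes not identifiable without negatively worded items")
  expect_error(arias_spec(rep("positive", 10)),
               "classes not identifiable without negatively worded items")
})

test_that("arias loadings are the fixed +/-1 pattern for any parameter value", {
  spec <- arias_spec(rses_polarity())
  for (s in 1:3) {
    set.seed(s)
    prm <- wordfx:::fma_map(spec, stats::rnorm(spec$n_struct))
    expect_identical(unname(prm$lambda[1, ]), rep(c(1, -1), c(5, 5)))
    expect_identical(unname(prm$lambda[2, ]), rep(1, 10))
    expect_identical(unname(prm$alpha), c(0, 0))
    expect_identical(prm$nu[1, ], prm$nu[2, ])
  }
})

test_that("steinmann sign and equality links hold exactly for any parameter value", {
  spec <- steinmann_spec(rses_polarity())
  set.seed(2)
  prm <- wordfx:::fma_map(spec, stats::rnorm(spec$n_struct))
  expect_identical(prm$lambda[1, spec$pos], prm$lambda[2, spec$pos])
  expect_identical(prm$lambda[1, spec$neg], -prm$lambda[2, spec$neg])
  expect_true(all(prm$lambda[2, ] > 0))
  expect_identical(prm$nu[1, spec$pos], prm$nu[2, spec$pos])
  expect_identical(unname(prm$alpha[2]), 0)
  expect_identical(unname(prm$phi[2]), 1)
  expect_true(all(prm$psi > 0))
})

test_that("M-step analytic gradient matches numerical differentiation", {
  sim <- generate_responses(generator_spec(seed = 4), n = 120,
                            continuous = TRUE)
  Y <- sim$responses
  post <- cbind(stats::runif(120, 0.1, 0.9))
  post <- cbind(post, 1 - post)
  W <- colSums(post)
  s <- lapply(1:2, function(k) colSums(Y * post[, k]))
  SS <- lapply(1:2, function(k) crossprod(Y * sqrt(post[, k])))
  for (mk in c("steinmann", "arias")) {
    spec <- if (mk == "steinmann") steinmann_spec(sim$polarity) else
      arias_spec(sim$polarity)
    set.seed(7)
    par <- stats::rnorm(spec$n_struct, 0, 0.3)
    g <- wordfx:::fma_q(spec, par, W, s, SS, grad = TRUE)$grad
    gn <- numDeriv::grad(function(x) wordfx:::fma_q(spec, x, W, s, SS), par)
    expect_lt(max(abs(g - gn)), 1e-6 * max(1, max(abs(gn))))
  }
})

test_that("EM loglikelihood is monotone and constraints survive fitting", {
  sim <- generate_responses(generator_spec(mechanism = "steinmann",
                                           mixing_weight = 0.12, seed = 14),
                            n = 500)
  fit <- fit_fma(sim$responses, steinmann_spec(sim$polarity),
                 n_starts = 10, n_final = 2, seed = 5)
  expect_true(all(diff(fit$ll_trace) > -1e-6))
  prm <- fit$parameters
  expect_lt(max(abs(prm$lambda[1, 6:10] + prm$lambda[2, 6:10])), 1e-8)
  expect_lt(max(abs(prm$lambda[1, 1:5] - prm$lambda[2, 1:5])), 1e-8)
  expect_identical(unname(prm$alpha[2]), 0)
  expect_identical(unname(prm$phi[2]), 1)
  expect_true(all(prm$psi > 0))
  expect_true(prm$mixing_weight > 0 && prm$mixing_weight < 1)
  # label identification is structural: class 1 negatives load negatively
  expect_true(all(prm$lambda[1, 6:10] < 0))
  # posteriors are proper
  expect_lt(max(abs(rowSums(fit$posteriors) - 1)), 1e-10)
  expect_true(fit$entropy >= 0 && fit$entropy <= 1)
  expect_true(is.finite(fit$loglik))
})

test_that("EM optimum matches a generic optimizer within 1e-4 loglik on a small instance", {
  sim <- generate_responses(generator_spec(mechanism = "arias", seed = 2,
                                           mixing_weight = 0.15),
                            n = 100, continuous = TRUE)
  spec <- arias_spec(sim$polarity)
  fit <- fit_fma(sim$responses, spec, n_starts = 30, n_final = 5, seed = 7)
  Y <- as.matrix(sim$responses)
  nll <- function(theta) {
    par <- theta[-length(theta)]
    pw <- stats::plogis(theta[length(theta)])
    prm <- wordfx:::fma_map(spec, par)
    ld <- wordfx:::fma_logdens(Y, prm)
    ld[, 1] <- ld[, 1] + log(pw)
    ld[, 2] <- ld[, 2] + log(1 - pw)
    -sum(wordfx:::row_logsumexp(ld))
  }
  # a BFGS polish of the EM solution must not find a better optimum
  polish <- stats::optim(c(fit$par, stats::qlogis(fit$parameters$mixing_weight)),
                         nll, method = "BFGS",
                         control = list(maxit = 2000, reltol = 1e-12))
  expect_lt(abs(-polish$value - fit$loglik), 1e-4)
  # independent BFGS runs from fresh random initializations cannot beat EM
  set.seed(31)
  best <- -Inf
  for (r in 1:5) {
    ini <- wordfx:::fma_init(Y, spec)
    o <- tryCatch(
      stats::optim(c(ini$par, stats::qlogis(ini$pw)), nll, method = "BFGS",
                   control = list(maxit = 2000, reltol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(o)) best <- max(best, -o$value)
  }
  expect_lt(best, fit$loglik + 1e-4)
})

test_that("single-fit recovery of the arias generating parameters", {
  sim <- generate_responses(
    generator_spec(mechanism = "arias", mixing_weight = 0.10, seed = 6),
    n = 2000, continuous = TRUE)
  fit <- fit_fma(sim$responses, arias_spec(sim$polarity),
                 n_starts = 10, n_final = 3, seed = 2)
  prm <- fit$parameters
  # generous single-replicate Monte-Carlo bounds (see the 200-replicate bias
  # study in test-acceptance.R for the tight version)
  expect_lt(abs(prm$mixing_weight - 0.10), 0.04)
  expect_lt(abs(prm$phi["inconsistent"] - 0.5), 0.12)
  expect_lt(abs(prm$phi["consistent"] - 1.0), 0.15)
})

test_that("entropy index matches its closed forms", {
  expect_identical(entropy_index(matrix(c(1, 0, 0, 1), 2, byrow = TRUE)), 1)
  expect_equal(entropy_index(matrix(0.5, 4, 2)), 0)
  post <- rbind(matrix(c(0.9, 0.1), 50, 2, byrow = TRUE),
                matrix(c(0.1, 0.9), 50, 2, byrow = TRUE))
  hand <- 1 - (-0.9 * log(0.9) - 0.1 * log(0.1)) / log(2)
  expect_equal(entropy_index(post), hand, tolerance = 1e-12)
  expect_equal(hand, 0.531, tolerance = 5e-4)
  expect_error(entropy_index(matrix(c(0.5, 0.4), 1)), "sum to 1")
})

test_that("kappa matches hand computation and band assignment", {
  f <- factor(rep(c("a", "b"), 10))
  expect_identical(cohen_kappa(f, f)$kappa, 1)
  expect_identical(cohen_kappa(f, f)$band, "almost perfect")
  a <- factor(rep(c("x", "x", "y", "y"), c(40, 10, 10, 40)))
  b <- factor(rep(c("x", "y", "x", "y"), c(40, 10, 10, 40)))
  k <- cohen_kappa(a, b)
  expect_equal(k$kappa, 0.6, tolerance = 1e-12)   # p_o = .8, p_e = .5
  expect_identical(k$band, "moderate")
  expect_error(cohen_kappa(f, f[1:3]), "same")
})

test_that("classification follows the modal rule with conservative ties", {
  cl <- classify(rbind(c(0.9, 0.1), c(0.1, 0.9), c(0.5, 0.5)))
  expect_identical(as.character(cl$class),
                   c("inconsistent", "consistent", "consistent"))
  expect_true(all(cl$posterior >= 0.5))
})

test_that("screening removes exactly the flagged rows and keeps identifiers", {
  X <- matrix(sample(1:4, 50, TRUE), 10, 5)
  rownames(X) <- paste0("r", 1:10)
  all_ok <- factor(rep("consistent", 10),
                   levels = c("inconsistent", "consistent"))
  kept <- screen_sample(X, all_ok)
  expect_length(attr(kept, "removed"), 0)
  attr(kept, "removed") <- NULL
  expect_identical(unname(kept), unname(X))
  flagged <- all_ok
  flagged[c(2, 7)] <- "inconsistent"
  out <- screen_sample(X, flagged)
  expect_identical(nrow(out), 8L)
  expect_identical(attr(out, "removed"), c("r2", "r7"))
  expect_error(screen_sample(X, flagged[1:5]), "cover all rows")
})

test_that("well-separated synthetic classes are recovered above 95% agreement", {
  sim <- generate_responses(
    generator_spec(mechanism = "steinmann", mixing_weight = 0.1,
                   loadings = rep(0.9, 10), neg_intercept_shift = -3,
                   seed = 11),
    n = 1500, continuous = TRUE)
  fit <- fit_fma(sim$responses, steinmann_spec(sim$polarity),
                 n_starts = 12, n_final = 3, seed = 3)
  expect_gt(mean(classify(fit)$class == sim$true_class), 0.95)
})

test_that("fit_fma validates dimensions and sample size", {
  pol <- rses_polarity()
  sim <- generate_responses(generator_spec(seed = 1), n = 60)
  expect_error(fit_fma(sim$responses[, 1:8], steinmann_spec(pol)),
               "expects 10")
  expect_error(fit_fma(sim$responses[1:30, ], steinmann_spec(pol)),
               "must exceed the number of free parameters")
})

test_that("standard S3 methods behave", {
  sim <- generate_responses(generator_spec(seed = 17, mixing_weight = 0.12),
                            n = 400)
  fit <- fit_fma(sim$responses, arias_spec(sim$polarity),
                 n_starts = 8, n_final = 2, seed = 4)
  expect_identical(predict(fit), fit$posteriors)
  post <- predict(fit, newdata = sim$responses[1:7, ])
  expect_identical(dim(post), c(7L, 2L))
  expect_lt(max(abs(rowSums(post) - 1)), 1e-10)
  expect_equal(as.numeric(logLik(fit)), fit$loglik)
  expect_identical(attr(logLik(fit), "df"), 23L)
  expect_identical(coef(fit), fit$parameters)
  Ysim <- simulate(fit, seed = 1)
  expect_identical(dim(Ysim), dim(as.matrix(sim$responses)))
  expect_identical(simulate(fit, seed = 1), Ysim)
  expect_output(print(fit), "Constrained factor mixture fit")
  expect_output(print(summary(fit)), "Standardized loadings")
  expect_identical(dim(standardized_loadings(fit)), c(2L, 10L))
  expect_true(all(abs(standardized_loadings(fit)) <= 1))
})
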