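# Model-implied covariance between two observed ordinal items whose latent
# responses are standard bivariate normal with correlation `rho`, scored
# 1..C: sum over the threshold grid of Phi2(ti, tj, rho) - Phi(ti) Phi(tj).
ordinal_cov <- function(ti, tj, rho) {
  if (length(ti) == 0 || length(tj) == 0) return(0)
  g <- expand.grid(a = ti, b = tj)
  sum(pbvn(g$a, g$b, rho) - stats::pnorm(g$a) * stats::pnorm(g$b))
}

#' Categorical (ordinal) omega reliability
#'
#' Model-based reliability of the ordinal sum score: loadings and thresholds
#' of a unidimensional standardized solution imply, through bivariate-normal
#' orthant probabilities, the covariances among the *observed* ordinal items;
#' omega is the implied true-score variance of the sum divided by the implied
#' total variance of the sum. A freed error covariance (`theta`, expressed as
#' a residual correlation between `theta_pair`) counts toward total variance
#' but not toward true-score variance (it is correlated error).
#'
#' @param loadings Standardized loadings per item.
#' @param thresholds List of per-item strictly increasing normal thresholds.
#' @param uniquenesses Optional residual variances; defaults to
#'   `1 - loadings^2`.
#' @param theta_pair,theta Optional freed error pair (indices or item names
#'   matching `names(loadings)`) and its standardized (correlation-metric)
#'   value.
#' @return Scalar omega.
#' @examples
#' tau <- rep(list(qnorm(c(0.25, 0.5, 0.75))), 5)
#' categorical_omega(rep(0.7, 5), tau)
#' @export
categorical_omega <- function(loadings, thresholds, uniquenesses = NULL,
                              theta_pair = NULL, theta = 0) {
  p <- length(loadings)
  stopifnot(length(thresholds) == p)
  ok <- vapply(thresholds, function(t) all(diff(t) > 0), logical(1))
  if (!all(ok)) stop("thresholds must be strictly increasing per item")
  if (is.null(uniquenesses)) uniquenesses <- 1 - loadings^2
  if (!is.null(theta_pair)) {
    if (is.character(theta_pair)) {
      theta_pair <- match(theta_pair, names(loadings))
    }
    theta_pair <- sort(as.integer(theta_pair))
  }
  true_var <- 0
  total_var <- 0
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      rho_t <- loadings[i] * loadings[j]
      rho_full <- if (i == j) 1 else rho_t
      if (!is.null(theta_pair) && i != j &&
          all(sort(c(i, j)) == theta_pair)) {
        rho_full <- rho_full +
          theta * sqrt(uniquenesses[i] * uniquenesses[j])
      }
      true_var <- true_var +
        ordinal_cov(thresholds[[i]], thresholds[[j]], min(max(rho_t, -1), 1))
      total_var <- total_var +
        ordinal_cov(thresholds[[i]], thresholds[[j]],
                    min(max(rho_full, -1), 1))
    }
  }
  if (total_var <= 0) return(0)
  true_var / total_var
}

#' Cronbach's alpha and item-rest correlations
#'
#' Continuous-treatment internal consistency on integer-coded items:
#' `alpha = p/(p - 1) * (1 - sum(var_i) / var(sum))`; the item-rest
#' correlation is each item's Pearson correlation with the sum of the
#' remaining items.
#'
#' @param data Response matrix or data frame.
#' @return List with `alpha` and named `item_rest` vector.
#' @examples
#' sim <- generate_responses(generator_spec(seed = 5, mixing_weight = 0),
#'                           n = 300)
#' cronbach_alpha(sim$responses)$alpha
#' @export
cronbach_alpha <- function(data) {
  X <- as_response_matrix(data)
  p <- ncol(X)
  if (p < 2) stop("at least two items are required")
  v <- apply(X, 2, stats::var)
  if (any(v == 0)) {
    nm <- colnames(X)
    if (is.null(nm)) nm <- paste0("item", seq_len(p))
    stop("zero-variance item: ", paste(nm[v == 0], collapse = ", "))
  }
  total <- rowSums(X)
  alpha <- p / (p - 1) * (1 - sum(v) / stats::var(total))
  item_rest <- vapply(seq_len(p), function(j) {
    stats::cor(X[, j], total - X[, j])
  }, numeric(1))
  names(item_rest) <- colnames(X)
  list(alpha = alpha, item_rest = item_rest)
}

#' BCa bootstrap confidence interval
#'
#' Bias-corrected and accelerated interval for a statistic of the rows of a
#' dataset, via [boot::boot()]. A degenerate bootstrap distribution (all
#' resampled values equal, or BCa correction unavailable) falls back to the
#' percentile interval with a warning; a constant statistic yields a
#' zero-width interval.
#'
#' @param data Matrix/data frame (rows resampled) or vector.
#' @param statistic Function of the resampled data returning a scalar.
#' @param n_boot Number of bootstrap samples.
#' @param method `"bca"` or `"percentile"`.
#' @param conf Confidence level.
#' @param seed Integer seed (resampling is deterministic given it).
#' @return List with `estimate`, `lower`, `upper`, `n_boot`, `method`.
#' @examples
#' bootstrap_ci(rnorm(50), mean, n_boot = 200, seed = 1)
#' @export
bootstrap_ci <- function(data, statistic, n_boot = 1000,
                         method = c("bca", "percentile"), conf = 0.95,
                         seed = NULL) {
  method <- match.arg(method)
  if (!is.null(seed)) set.seed(seed)
  vec <- is.null(dim(data))
  stat_fun <- function(d, idx) {
    statistic(if (vec) d[idx] else d[idx, , drop = FALSE])
  }
  b <- boot::boot(data, stat_fun, R = n_boot)
  est <- b$t0
  if (stats::sd(b$t) < .Machine$double.eps^0.5) {
    if (diff(range(b$t)) == 0 && b$t[1] == est) {
      return(list(estimate = est, lower = est, upper = est,
                  n_boot = n_boot, method = "degenerate"))
    }
  }
  ci <- NULL
  if (method == "bca") {
    ci <- tryCatch(boot::boot.ci(b, conf = conf, type = "bca"),
                   error = function(e) NULL)
    if (!is.null(ci)) {
      return(list(estimate = est, lower = ci$bca[4], upper = ci$bca[5],
                  n_boot = n_boot, method = "bca"))
    }
    warning("BCa interval unavailable; falling back to percentile")
  }
  q <- stats::quantile(b$t, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                       names = FALSE)
  list(estimate = est, lower = q[1], upper = q[2], n_boot = n_boot,
       method = "percentile")
}

#' Internal-consistency report for a screened ordinal scale
#'
#' Convenience wrapper computing categorical omega (from a one-factor
#' least-squares CFA on the polychoric matrix, with and without the freed
#' error covariance when `theta_pair` is given), Cronbach's alpha, item-rest
#' correlations, and BCa bootstrap intervals for omega and alpha.
#'
#' @param data Ordinal response matrix.
#' @param polarity Item polarity map (used only to build the CFA spec).
#' @param theta_pair Optional freed error pair, as in [cfa_spec()].
#' @param n_boot Bootstrap samples for the intervals (0 skips them).
#' @param seed Integer seed for the bootstrap.
#' @return Object of class `reliability_result`.
#' @export
scale_reliability <- function(data, polarity, theta_pair = NULL,
                              n_boot = 1000, seed = NULL) {
  X <- as_response_matrix(data)
  omega_of <- function(M, pair) {
    pc <- polychoric(M)
    spec <- cfa_spec("one_factor", polarity, theta_pair = pair)
    fit <- fit_cfa(pc$matrix, nrow(M), spec)
    categorical_omega(fit$loadings, pc$thresholds,
                      uniquenesses = fit$uniquenesses,
                      theta_pair = pair,
                      theta = if (is.null(pair)) 0 else fit$theta_standardized)
  }
  al <- cronbach_alpha(X)
  out <- list(
    omega_categorical = omega_of(X, NULL),
    omega_categorical_theta = if (!is.null(theta_pair)) {
      omega_of(X, theta_pair)
    },
    alpha = al$alpha,
    item_rest = al$item_rest,
    n_boot = n_boot, seed = seed
  )
  if (n_boot > 0) {
    out$omega_ci <- bootstrap_ci(X, function(M) omega_of(M, NULL),
                                 n_boot = n_boot, seed = seed)
    out$alpha_ci <- bootstrap_ci(X, function(M) cronbach_alpha(M)$alpha,
                                 n_boot = n_boot, seed = seed)
  }
  structure(out, class = "reliability_result")
}

#' @export
print.reliability_result <- function(x, digits = 2, ...) {
  fmt_ci <- function(ci) {
    if (is.null(ci)) return("")
    sprintf(" (95%% CI %.*f, %.*f)", digits, ci$lower, digits, ci$upper)
  }
  cat(sprintf("categorical omega = %.*f%s\n", digits, x$omega_categorical,
              fmt_ci(x$omega_ci)))
  if (!is.null(x$omega_categorical_theta)) {
    cat(sprintf("categorical omega (free error covariance) = %.*f\n",
                digits, x$omega_categorical_theta))
  }
  cat(sprintf("alpha = %.*f%s\n", digits, x$alpha, fmt_ci(x$alpha_ci)))
  cat("item-rest correlations:\n")
  print(round(x$item_rest, digits))
  invisible(x)
}
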