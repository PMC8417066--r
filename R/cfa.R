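#' Specify a confirmatory factor model for a mixed-worded scale
#'
#' Three structures are supported for a scale with positively and (recoded)
#' negatively worded items measuring one trait:
#' \describe{
#'   \item{`one_factor`}{all items load freely on a single standardized
#'     factor;}
#'   \item{`two_factor`}{positive and negative items load on separate
#'     standardized factors with a free factor correlation;}
#'   \item{`riifa`}{random-intercept item factor analysis: one substantive
#'     factor with free loadings plus an orthogonal method factor whose
#'     unstandardized loadings are fixed at +1 (positive items) and -1
#'     (recoded negative items), with a free method-factor variance. The
#'     method factor absorbs uniform response-style (acquiescence) variance.}
#' }
#' An optional error covariance (`theta_pair`) between one item pair can be
#' freed in any structure.
#'
#' @param kind Model kind.
#' @param polarity Character vector (`"positive"`/`"negative"`) per item.
#' @param theta_pair Optional length-2 vector (item names or indices) whose
#'   error covariance is freed.
#' @return Object of class `cfa_spec`.
#' @examples
#' spec <- cfa_spec("two_factor", rses_polarity(), theta_pair = c("p4", "p5"))
#' spec$df   # 33 for 10 items
#' @export
cfa_spec <- function(kind = c("one_factor", "two_factor", "riifa"),
                     polarity, theta_pair = NULL) {
  kind <- match.arg(kind)
  p <- length(polarity)
  polarity <- check_polarity(polarity, p)
  items <- names(polarity)
  if (is.null(items)) items <- paste0("item", seq_len(p))
  if (kind == "riifa" && !any(polarity == "negative")) {
    stop("a RIIFA method factor requires negatively worded items")
  }
  if (!is.null(theta_pair)) {
    if (is.character(theta_pair)) theta_pair <- match(theta_pair, items)
    theta_pair <- sort(as.integer(theta_pair))
    if (length(theta_pair) != 2 || anyNA(theta_pair)) {
      stop("theta_pair must identify exactly two items")
    }
  }
  n_free <- p + switch(kind, one_factor = 0L, two_factor = 1L, riifa = 1L) +
    (!is.null(theta_pair))
  structure(list(kind = kind, polarity = polarity, items = items, p = p,
                 theta_pair = theta_pair, n_free = n_free,
                 df = p * (p - 1) / 2 - n_free),
            class = "cfa_spec")
}

# Unpack the free-parameter vector of a cfa_spec.
cfa_unpack <- function(spec, par) {
  p <- spec$p
  lambda <- par[seq_len(p)]
  i <- p
  phi <- v <- theta <- NULL
  if (spec$kind == "two_factor") { phi <- tanh(par[i + 1]); i <- i + 1 }
  if (spec$kind == "riifa") { v <- exp(par[i + 1]); i <- i + 1 }
  if (!is.null(spec$theta_pair)) theta <- par[i + 1]
  list(lambda = lambda, phi = phi, v = v, theta = theta)
}

# Model-implied correlation matrix (unit diagonal by construction) for a
# cfa_spec. `extra` optionally frees one more parameter (for score tests):
# list(type = "errcov"|"crossload", idx = c(i, j) or i, value).
cfa_implied <- function(spec, est, extra = NULL) {
  p <- spec$p
  lam <- est$lambda
  pos <- spec$polarity == "positive"
  Sigma <- tcrossprod(lam)
  if (spec$kind == "two_factor") {
    cross <- outer(pos, pos, "!=")
    Sigma[cross] <- Sigma[cross] * est$phi
  }
  s <- ifelse(pos, 1, -1)
  if (spec$kind == "riifa") Sigma <- Sigma + est$v * tcrossprod(s)
  if (!is.null(est$theta)) {
    ij <- spec$theta_pair
    Sigma[ij[1], ij[2]] <- Sigma[ij[1], ij[2]] + est$theta
    Sigma[ij[2], ij[1]] <- Sigma[ij[1], ij[2]]
  }
  if (!is.null(extra)) {
    if (extra$type == "errcov") {
      ij <- extra$idx
      Sigma[ij[1], ij[2]] <- Sigma[ij[1], ij[2]] + extra$value
      Sigma[ij[2], ij[1]] <- Sigma[ij[1], ij[2]]
    } else if (extra$type == "crossload") {
      # item `extra$idx` gains a loading on the other substantive factor
      i <- extra$idx
      other <- xor(pos, pos[i])
      add <- numeric(p)
      add[other] <- extra$value * lam[other]
      add[!other] <- extra$value * lam[!other] * est$phi
      add[i] <- 0
      Sigma[i, ] <- Sigma[i, ] + add
      Sigma[, i] <- Sigma[i, ]
    }
  }
  diag(Sigma) <- 1
  Sigma
}

# Communalities implied by the estimates (orthogonal factors; the 2F cross
# terms vanish because each item loads on a single substantive factor).
cfa_h2 <- function(spec, est) {
  h2 <- est$lambda^2
  if (spec$kind == "riifa") h2 <- h2 + est$v
  h2
}

#' Fit a confirmatory factor model to a correlation matrix
#'
#' Point estimation minimizes a least-squares discrepancy between the
#' observed (polychoric) correlations and the model-implied correlation
#' structure over the strict lower triangle. The default estimator is
#' diagonally weighted least squares with normal-theory weights
#' `(1 - r^2)^2` (the large-sample variance of a correlation up to `1/n`),
#' the same estimator family used by categorical-data SEM software;
#' `estimator = "uls"` gives unweighted least squares. The chi-square used
#' for fit indices is the normal-theory ML discrepancy `(n - 1) * F_ML`
#' evaluated at the least-squares solution; when the input is a polychoric
#' matrix this is an approximation to, not a reproduction of, scaled
#' categorical-estimator test statistics.
#'
#' @param R Correlation matrix, `polychoric` object, or raw ordinal response
#'   matrix (polychorics are then computed first).
#' @param n Sample size behind `R`.
#' @param spec A [cfa_spec()].
#' @param estimator `"dwls"` (default) or `"uls"`.
#' @param weights Optional vector of asymptotic variances for the lower
#'   triangle (column-major order) to use as DWLS weights in place of the
#'   normal-theory approximation.
#' @return Object of class `cfa_fit` with standardized loadings,
#'   communalities, the factor correlation or method loading where defined,
#'   the standardized error correlation for the freed pair, and fit indices
#'   (`chi_square`, `df`, `CFI`, `TLI`, `RMSEA` with 90% CI, `SRMR`).
#' @examples
#' tot <- rses_polychoric("total")
#' f <- fit_cfa(tot$matrix, n = tot$n,
#'              cfa_spec("two_factor", rses_polarity(), c("p4", "p5")))
#' round(f$factor_correlation, 2)
#' @export
fit_cfa <- function(R, n, spec, estimator = c("dwls", "uls"),
                    weights = NULL) {
  estimator <- match.arg(estimator)
  if (inherits(R, "polychoric")) R <- R$matrix
  if (is.matrix(R) && nrow(R) != ncol(R)) R <- polychoric(R)$matrix
  R <- as.matrix(R)
  if (nrow(R) != ncol(R) || any(abs(diag(R) - 1) > 1e-8)) {
    if (nrow(R) == ncol(R)) stop("R must have a unit diagonal")
    stop("R must be square")
  }
  p <- spec$p
  if (ncol(R) != p) stop("R dimension does not match the model spec")
  if (n <= p) stop("sample size must exceed the number of items")
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) < -1e-8) stop("R must be positive semi-definite")
  low <- lower.tri(R)
  w <- if (estimator == "uls") {
    rep(1, sum(low))
  } else if (is.null(weights)) {
    (1 - R[low]^2)^2
  } else {
    if (length(weights) != sum(low) || any(weights <= 0)) {
      stop("weights must be ", sum(low), " positive asymptotic variances")
    }
    weights
  }
  f_uls <- function(par) {
    est <- cfa_unpack(spec, par)
    sum((R[low] - cfa_implied(spec, est)[low])^2 / w)
  }
  # start: scaled first principal component, mild extras
  l0 <- ev$vectors[, 1] * sqrt(ev$values[1])
  l0 <- abs(l0) * 0.9
  par0 <- c(l0,
            if (spec$kind == "two_factor") atanh(0.5),
            if (spec$kind == "riifa") log(0.05),
            if (!is.null(spec$theta_pair)) 0)
  opt <- stats::optim(par0, f_uls, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-14))
  if (opt$convergence != 0) {
    g <- numDeriv::grad(f_uls, opt$par)
    stop("CFA did not converge; gradient norm ", signif(sqrt(sum(g^2)), 3))
  }
  est <- cfa_unpack(spec, opt$par)
  h2 <- cfa_h2(spec, est)
  if (any(h2 > 1)) {
    warning("Heywood case: communality above 1 for item(s) ",
            paste(spec$items[h2 > 1], collapse = ", "))
  }
  psi <- 1 - h2
  Sigma <- cfa_implied(spec, est)
  theta_std <- NULL
  if (!is.null(est$theta)) {
    ij <- spec$theta_pair
    theta_std <- est$theta / sqrt(max(psi[ij[1]], 1e-12) *
                                  max(psi[ij[2]], 1e-12))
  }
  fit <- structure(list(
    spec = spec, n = n, R = R, par = opt$par, estimator = estimator,
    loadings = stats::setNames(est$lambda, spec$items),
    factor_correlation = est$phi,
    method_variance = est$v,
    method_loading = if (!is.null(est$v)) sqrt(est$v),
    theta = est$theta, theta_standardized = theta_std,
    communalities = stats::setNames(h2, spec$items),
    uniquenesses = stats::setNames(psi, spec$items),
    implied = Sigma, discrepancy = opt$value,
    residuals = R - Sigma, df = spec$df
  ), class = "cfa_fit")
  c(fit, fit_indices(fit))
}

# ML discrepancy between a sample correlation matrix and an implied matrix.
f_ml <- function(S, Sigma) {
  p <- ncol(S)
  ch <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(ch)) return(NA_real_)
  ld <- 2 * sum(log(diag(ch)))
  lds <- determinant(S, logarithm = TRUE)$modulus
  ld - as.numeric(lds) + sum(diag(chol2inv(ch) %*% S)) - p
}

#' Fit indices for a fitted factor model
#'
#' CFI, TLI, RMSEA (with a 90\% confidence interval from noncentral
#' chi-square inversion), and SRMR, computed from the normal-theory ML
#' chi-square against a zero-correlation independence baseline. TLI is
#' truncated at 1, so a perfectly fitting model reports exactly 1.
#'
#' @param fit A `cfa_fit`.
#' @param baseline Optional independence-model statistics (list with
#'   `chi_square`, `df`); computed from `fit`'s sample matrix when omitted.
#' @return Named list of indices.
#' @export
fit_indices <- function(fit, baseline = NULL) {
  n <- fit$n
  p <- ncol(fit$R)
  chi <- (n - 1) * f_ml(fit$R, fit$implied)
  df <- fit$df
  if (is.null(baseline)) {
    baseline <- list(chi_square = (n - 1) * f_ml(fit$R, diag(p)),
                     df = p * (p - 1) / 2)
  }
  srmr <- sqrt(mean(fit$residuals[lower.tri(fit$residuals)]^2))
  index_arithmetic(chi, df, baseline$chi_square, baseline$df, n, srmr)
}

# The index formulas themselves, separated from the chi-square computation
# so they can be checked against hand-evaluated values.
index_arithmetic <- function(chi, df, chib, dfb, n, srmr) {
  if (df == 0) {
    cfi <- 1; tli <- 1; rmsea <- 0; ci <- c(0, 0)
  } else {
    num <- max(chi - df, 0)
    cfi <- 1 - num / max(chib - dfb, chi - df, 0)
    # truncated at 1 so a perfect fit reports TLI = 1
    tli <- min(((chib / dfb) - (chi / df)) / ((chib / dfb) - 1), 1)
    rmsea <- sqrt(num / (df * (n - 1)))
    ci <- rmsea_ci(chi, df, n)
  }
  list(chi_square = chi, CFI = cfi, TLI = tli, RMSEA = rmsea,
       RMSEA_lo = ci[1], RMSEA_hi = ci[2], SRMR = srmr,
       baseline_chi_square = chib, baseline_df = dfb)
}

# 90% RMSEA confidence interval by inverting the noncentral chi-square.
rmsea_ci <- function(chi, df, n, level = 0.90) {
  a <- (1 - level) / 2
  ncp_root <- function(prob) {
    if (stats::pchisq(chi, df) < prob) return(0)
    stats::uniroot(function(nc) stats::pchisq(chi, df, ncp = nc) - prob,
                   lower = 0, upper = max(chi * 2, 10),
                   extendInt = "downX", tol = 1e-8)$root
  }
  lo <- ncp_root(1 - a)
  hi <- ncp_root(a)
  sqrt(c(lo, hi) / (df * (n - 1)))
}

#' Modification indices with standardized expected parameter change
#'
#' For every fixed error covariance (and, in the two-factor model, every
#' fixed cross-loading) the modification index is the expected chi-square
#' drop from freeing that parameter, computed by re-minimizing the
#' estimation discrepancy with the single parameter freed (starting from the
#' fitted solution) and differencing the ML chi-squares. The expected
#' parameter change (EPC) is the freed estimate; error-covariance SEPCs are
#' expressed as residual correlations (EPC divided by the square root of the
#' product of the freed solution's uniquenesses), cross-loading SEPCs are
#' already in the standardized metric.
#'
#' @param fit A `cfa_fit`.
#' @return Data frame sorted by decreasing MI with columns `parameter`,
#'   `type`, `mi`, `epc`, `sepc`.
#' @export
modification_indices <- function(fit) {
  spec <- fit$spec
  p <- spec$p
  S <- fit$R
  low <- lower.tri(S)
  w <- if (fit$estimator == "uls") rep(1, sum(low)) else (1 - S[low]^2)^2
  pairs <- which(low, arr.ind = TRUE)
  cand <- lapply(seq_len(nrow(pairs)), function(r) {
    list(type = "errcov", idx = c(pairs[r, 2], pairs[r, 1]))
  })
  if (!is.null(spec$theta_pair)) {
    keep <- !vapply(cand, function(cd) {
      all(sort(cd$idx) == spec$theta_pair)
    }, logical(1))
    cand <- cand[keep]
  }
  if (spec$kind == "two_factor") {
    cand <- c(cand, lapply(seq_len(p),
                           function(i) list(type = "crossload", idx = i)))
  }
  k <- length(fit$par)
  rows <- lapply(cand, function(cd) {
    f_ext <- function(pe) {
      est <- cfa_unpack(spec, pe[seq_len(k)])
      cd$value <- pe[k + 1]
      sum((S[low] - cfa_implied(spec, est, extra = cd)[low])^2 / w)
    }
    opt <- stats::optim(c(fit$par, 0), f_ext, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-12))
    est <- cfa_unpack(spec, opt$par[seq_len(k)])
    gamma <- opt$par[k + 1]
    cd$value <- gamma
    chi_freed <- (fit$n - 1) * f_ml(S, cfa_implied(spec, est, extra = cd))
    h2 <- cfa_h2(spec, est)
    if (cd$type == "crossload") {
      other <- xor(spec$polarity == "positive",
                   spec$polarity[cd$idx] == "positive")
      h2[cd$idx] <- h2[cd$idx] + gamma^2 +
        2 * gamma * est$lambda[cd$idx] * est$phi
    }
    psi <- pmax(1 - h2, 1e-12)
    sepc <- if (cd$type == "errcov") {
      gamma / sqrt(prod(psi[cd$idx]))
    } else gamma
    data.frame(mi = max(fit$chi_square - chi_freed, 0), epc = gamma,
               sepc = sepc)
  })
  out <- do.call(rbind, rows)
  out$type <- vapply(cand, `[[`, character(1), "type")
  out$parameter <- vapply(cand, function(cd) {
    if (cd$type == "errcov") {
      paste(spec$items[cd$idx], collapse = "~~")
    } else paste0(spec$items[cd$idx], "=~other")
  }, character(1))
  out <- out[order(-out$mi), c("parameter", "type", "mi", "epc", "sepc")]
  rownames(out) <- NULL
  out
}

#' @export
print.cfa_fit <- function(x, digits = 3, ...) {
  cat("Least-squares CFA (", x$spec$kind,
      if (!is.null(x$spec$theta_pair)) paste0(
        ", free error covariance ",
        paste(x$spec$items[x$spec$theta_pair], collapse = "-")),
      "), ", x$spec$p, " items, n = ", x$n, "\n", sep = "")
  cat("Standardized loadings:\n")
  print(round(x$loadings, digits))
  if (!is.null(x$factor_correlation)) {
    cat("Factor correlation:", round(x$factor_correlation, digits), "\n")
  }
  if (!is.null(x$method_loading)) {
    cat("Standardized method loading (|.|):",
        round(x$method_loading, digits), "\n")
  }
  if (!is.null(x$theta_standardized)) {
    cat("Standardized error correlation:",
        round(x$theta_standardized, digits), "\n")
  }
  cat(sprintf("chi2(%d) = %.2f, CFI = %.3f, TLI = %.3f, RMSEA = %.3f (%.3f, %.3f), SRMR = %.3f\n",
              x$df, x$chi_square, x$CFI, x$TLI, x$RMSEA, x$RMSEA_lo,
              x$RMSEA_hi, x$SRMR))
  invisible(x)
}

# `fit_cfa` returns c(fit, fit_indices(fit)) which drops the class; restore.
#' @noRd
c.cfa_fit <- function(...) {
  out <- NextMethod()
  class(out) <- "cfa_fit"
  out
}
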