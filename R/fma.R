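#' Constrained factor mixture specifications for wording-effects screening
#'
#' Both specifications posit two latent classes sharing a one-factor
#' structure: class 1 collects *inconsistent* respondents, whose recoded
#' negatively worded items load with flipped sign, and class 2 collects
#' *consistent* respondents. Because the sign flip is built into the
#' structure, the class labels are identified by construction and cannot
#' switch.
#'
#' `steinmann_spec()` (sign-flip parameterization): positive-item loadings
#' and intercepts are shared across classes with a positivity bound; the
#' consistent-class negative loadings are free and positive, the
#' inconsistent-class negative loadings are their exact negatives; negative
#' intercepts are class-specific; the consistent class is the reference
#' (factor mean 0, variance 1) while the inconsistent class has free factor
#' mean and variance; uniquenesses are shared. 38 free parameters for a
#' 5 + 5 scale.
#'
#' `arias_spec()` (random-intercept parameterization): all loadings are
#' fixed at +1 except the inconsistent-class negative loadings, fixed at -1;
#' intercepts are shared across classes, both factor means are 0, both
#' factor variances are free, uniquenesses shared. 23 free parameters for a
#' 5 + 5 scale.
#'
#' @param item_polarity Character vector (`"positive"`/`"negative"`) per
#'   item, optionally named by item.
#' @return Object of class `fma_spec`.
#' @examples
#' steinmann_spec(rses_polarity())$n_free  # 38
#' arias_spec(rses_polarity())$n_free      # 23
#' @export
steinmann_spec <- function(item_polarity) {
  new_fma_spec("steinmann", item_polarity)
}

#' @rdname steinmann_spec
#' @export
arias_spec <- function(item_polarity) {
  new_fma_spec("arias", item_polarity)
}

new_fma_spec <- function(model, item_polarity) {
  p <- length(item_polarity)
  polarity <- check_polarity(item_polarity, p)
  items <- names(polarity)
  if (is.null(items)) items <- paste0("item", seq_len(p))
  pos <- which(polarity == "positive")
  neg <- which(polarity == "negative")
  if (length(neg) == 0) {
    stop("classes not identifiable without negatively worded items")
  }
  if (length(pos) == 0) {
    stop("at least one positively worded item is required")
  }
  a <- length(pos); b <- length(neg)
  n_struct <- as.integer(switch(model,
                                steinmann = 2 * p + a + 2 * b + 2,
                                arias = 2 * p + 2))
  structure(list(model = model, polarity = polarity, items = items, p = p,
                 pos = pos, neg = neg, n_struct = n_struct,
                 n_free = n_struct + 1L, n_classes = 2L),
            class = "fma_spec")
}

#' @export
print.fma_spec <- function(x, ...) {
  cat("Constrained 2-class factor mixture spec (", x$model, "), ",
      length(x$pos), " positive + ", length(x$neg), " negative items, ",
      x$n_free, " free parameters\n", sep = "")
  invisible(x)
}

# Map the unconstrained structural parameter vector onto the model
# parameters (lambda, nu: 2 x p; psi: p; alpha, phi: length 2). Positivity
# bounds are log-parameterized; equality and sign links are applied here so
# they hold exactly for any parameter vector.
fma_map <- function(spec, par) {
  p <- spec$p; pos <- spec$pos; neg <- spec$neg
  a <- length(pos); b <- length(neg)
  lambda <- matrix(0, 2, p); nu <- matrix(0, 2, p)
  if (spec$model == "steinmann") {
    lp <- exp(par[seq_len(a)])
    ln <- exp(par[a + seq_len(b)])
    i <- a + b
    nup <- par[i + seq_len(a)]; i <- i + a
    nu1n <- par[i + seq_len(b)]; i <- i + b
    nu2n <- par[i + seq_len(b)]; i <- i + b
    psi <- exp(par[i + seq_len(p)]); i <- i + p
    alpha <- c(par[i + 1], 0)
    phi <- c(exp(par[i + 2]), 1)
    lambda[, pos] <- rep(lp, each = 2)
    lambda[1, neg] <- -ln
    lambda[2, neg] <- ln
    nu[, pos] <- rep(nup, each = 2)
    nu[1, neg] <- nu1n
    nu[2, neg] <- nu2n
  } else {
    nuv <- par[seq_len(p)]
    psi <- exp(par[p + seq_len(p)])
    phi <- exp(par[2 * p + 1:2])
    alpha <- c(0, 0)
    lambda[, ] <- 1
    lambda[1, neg] <- -1
    nu[1, ] <- nu[2, ] <- nuv
  }
  list(lambda = lambda, nu = nu, psi = psi, alpha = alpha, phi = phi)
}

# Chain rule back from gradients in model-parameter space to the
# unconstrained vector. `g` carries glambda, gnu (2 x p), gpsi (p),
# galpha, gphi (length 2).
fma_map_grad <- function(spec, par, prm, g) {
  p <- spec$p; pos <- spec$pos; neg <- spec$neg
  a <- length(pos); b <- length(neg)
  if (spec$model == "steinmann") {
    lp <- prm$lambda[2, pos]; ln <- prm$lambda[2, neg]
    out <- numeric(spec$n_struct)
    out[seq_len(a)] <- lp * (g$glambda[1, pos] + g$glambda[2, pos])
    out[a + seq_len(b)] <- ln * (g$glambda[2, neg] - g$glambda[1, neg])
    i <- a + b
    out[i + seq_len(a)] <- g$gnu[1, pos] + g$gnu[2, pos]; i <- i + a
    out[i + seq_len(b)] <- g$gnu[1, neg]; i <- i + b
    out[i + seq_len(b)] <- g$gnu[2, neg]; i <- i + b
    out[i + seq_len(p)] <- prm$psi * g$gpsi; i <- i + p
    out[i + 1] <- g$galpha[1]
    out[i + 2] <- prm$phi[1] * g$gphi[1]
  } else {
    out <- c(g$gnu[1, ] + g$gnu[2, ],
             prm$psi * g$gpsi,
             prm$phi * g$gphi)
  }
  out
}

# Expected complete-data loglikelihood (up to the mixing term) and its
# gradient, from per-class sufficient statistics:
# W[k] = sum of posteriors, s[[k]] = sum of weighted responses,
# SS[[k]] = sum of weighted outer products.
fma_q <- function(spec, par, W, s, SS, grad = FALSE) {
  prm <- fma_map(spec, par)
  p <- spec$p
  q <- 0
  if (grad) {
    glambda <- gnu <- matrix(0, 2, p)
    gpsi <- numeric(p); galpha <- gphi <- numeric(2)
  }
  for (k in 1:2) {
    lam <- prm$lambda[k, ]
    mu <- prm$nu[k, ] + prm$alpha[k] * lam
    Sigma <- prm$phi[k] * tcrossprod(lam) + diag(prm$psi, p)
    ch <- tryCatch(chol(Sigma), error = function(e) NULL)
    if (is.null(ch)) return(if (grad) list(q = -Inf) else -Inf)
    A <- chol2inv(ch)
    C <- SS[[k]] - tcrossprod(s[[k]], mu) - tcrossprod(mu, s[[k]]) +
      W[k] * tcrossprod(mu)
    q <- q - 0.5 * (W[k] * (p * log(2 * pi) + 2 * sum(log(diag(ch)))) +
                      sum(A * C))
    if (grad) {
      G <- -0.5 * (W[k] * A - A %*% C %*% A)
      gmu <- as.numeric(A %*% (s[[k]] - W[k] * mu))
      glambda[k, ] <- 2 * prm$phi[k] * as.numeric(G %*% lam) +
        prm$alpha[k] * gmu
      gnu[k, ] <- gmu
      gpsi <- gpsi + diag(G)
      galpha[k] <- sum(lam * gmu)
      gphi[k] <- as.numeric(lam %*% G %*% lam)
    }
  }
  if (!grad) return(q)
  list(q = q,
       grad = fma_map_grad(spec, par, prm,
                           list(glambda = glambda, gnu = gnu, gpsi = gpsi,
                                galpha = galpha, gphi = gphi)))
}

# Per-class Gaussian log densities of the data rows: n x 2 matrix.
fma_logdens <- function(Y, prm) {
  p <- ncol(Y)
  out <- matrix(0, nrow(Y), 2)
  for (k in 1:2) {
    lam <- prm$lambda[k, ]
    mu <- prm$nu[k, ] + prm$alpha[k] * lam
    Sigma <- prm$phi[k] * tcrossprod(lam) + diag(prm$psi, p)
    ch <- chol(Sigma)
    z <- sweep(Y, 2, mu) %*% backsolve(ch, diag(p))
    out[, k] <- -0.5 * (p * log(2 * pi) + 2 * sum(log(diag(ch))) +
                          rowSums(z^2))
  }
  out
}

# One EM run from a given start; returns loglik trace and final state.
fma_em <- function(Y, spec, par, pw, max_iter, tol, inner_maxit = 100) {
  n <- nrow(Y)
  floor_w <- 1 / (2 * n)
  ll_old <- -Inf
  ll_trace <- numeric(0)
  floored <- FALSE
  for (iter in seq_len(max_iter)) {
    prm <- fma_map(spec, par)
    ld <- fma_logdens(Y, prm)
    lp <- sweep(ld, 2, log(c(pw, 1 - pw)), "+")
    llr <- row_logsumexp(lp)
    ll <- sum(llr)
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) break
    ll_old <- ll
    post <- exp(lp - llr)
    pw_new <- mean(post[, 1])
    if (pw_new < floor_w || pw_new > 1 - floor_w) {
      pw_new <- min(max(pw_new, floor_w), 1 - floor_w)
      floored <- TRUE
    }
    pw <- pw_new
    W <- colSums(post)
    s <- lapply(1:2, function(k) colSums(Y * post[, k]))
    SS <- lapply(1:2, function(k) crossprod(Y * sqrt(post[, k])))
    opt <- stats::optim(par,
                        fn = function(x) -fma_q(spec, x, W, s, SS),
                        gr = function(x) -fma_q(spec, x, W, s, SS,
                                                grad = TRUE)$grad,
                        method = "BFGS",
                        control = list(maxit = inner_maxit))
    par <- opt$par
  }
  prm <- fma_map(spec, par)
  ld <- fma_logdens(Y, prm)
  lp <- sweep(ld, 2, log(c(pw, 1 - pw)), "+")
  llr <- row_logsumexp(lp)
  list(par = par, pw = pw, loglik = sum(llr),
       posteriors = exp(lp - llr), ll_trace = ll_trace,
       n_iter = length(ll_trace), floored = floored,
       converged = length(ll_trace) < max_iter)
}

# Random perturbed initialization around data moments.
fma_init <- function(Y, spec) {
  p <- ncol(Y)
  cm <- colMeans(Y)
  cv <- apply(Y, 2, stats::var)
  pc <- eigen(stats::cov(Y), symmetric = TRUE)
  l0 <- abs(pc$vectors[, 1] * sqrt(pc$values[1]))
  if (spec$model == "steinmann") {
    a <- length(spec$pos); b <- length(spec$neg)
    par <- c(log(pmax(l0[spec$pos], 0.1)) + stats::rnorm(a, 0, 0.4),
             log(pmax(l0[spec$neg], 0.1)) + stats::rnorm(b, 0, 0.4),
             cm[spec$pos] + stats::rnorm(a, 0, 0.3 * sqrt(cv[spec$pos])),
             cm[spec$neg] + stats::rnorm(b, 0, 0.8 * sqrt(cv[spec$neg])),
             cm[spec$neg] + stats::rnorm(b, 0, 0.3 * sqrt(cv[spec$neg])),
             log(pmax(cv / 2, 0.05)) + stats::rnorm(p, 0, 0.4),
             stats::rnorm(1, 0, 0.5),
             stats::rnorm(1, 0, 0.5))
  } else {
    par <- c(cm + stats::rnorm(p, 0, 0.3 * sqrt(cv)),
             log(pmax(cv / 2, 0.05)) + stats::rnorm(p, 0, 0.4),
             stats::rnorm(2, log(0.5), 0.6))
  }
  list(par = par, pw = stats::runif(1, 0.05, 0.3))
}

#' Fit a constrained two-class factor mixture model
#'
#' Maximizes the two-component Gaussian-mixture loglikelihood (items treated
#' as continuous; ordinal inputs are consumed as their integer codes) under
#' the equality and sign constraints of the chosen specification, via EM
#' whose M-step maximizes the expected complete-data loglikelihood with an
#' analytic-gradient quasi-Newton solver. A multistart scheme protects
#' against local optima: `n_starts` random perturbed initializations are run
#' for a few EM iterations, the best `n_final` are iterated to convergence,
#' and the number of final runs replicating the best loglikelihood (within
#' 0.01) is reported so users can judge whether to raise the start count.
#'
#' @param data Numeric matrix or data frame of item responses.
#' @param spec An [steinmann_spec()] or [arias_spec()] object.
#' @param n_starts Initial-stage random starts.
#' @param n_final Starts iterated to full convergence.
#' @param seed Integer seed controlling the random starts.
#' @param max_iter,tol EM iteration cap and absolute loglikelihood
#'   convergence tolerance.
#' @param init_iter EM iterations in the initial multistart stage.
#' @return Object of class `fma_fit` with elements `parameters` (loadings,
#'   intercepts, uniquenesses, factor means/variances per class, mixing
#'   weight of the inconsistent class), `loglik`, `posteriors`, `entropy`,
#'   `n_free_parameters`, `best_loglik_replications`, `converged`.
#' @examples
#' sim <- generate_responses(generator_spec(seed = 3), n = 200)
#' fit <- fit_fma(sim$responses, arias_spec(rses_polarity()),
#'                n_starts = 10, n_final = 2, seed = 1)
#' fit$parameters$mixing_weight
#' @export
fit_fma <- function(data, spec, n_starts = 200, n_final = 20, seed = NULL,
                    max_iter = 5000, tol = 1e-7, init_iter = 30) {
  stopifnot(inherits(spec, "fma_spec"))
  Y <- as_response_matrix(data)
  storage.mode(Y) <- "double"
  n <- nrow(Y)
  if (ncol(Y) != spec$p) stop("data has ", ncol(Y), " items but the spec ",
                              "expects ", spec$p)
  if (n <= spec$n_free) {
    stop("sample size (", n, ") must exceed the number of free parameters (",
         spec$n_free, ")")
  }
  if (!is.null(seed)) set.seed(seed)
  n_final <- min(n_final, n_starts)
  # stage 1: short EM runs from random starts
  stage1 <- vector("list", n_starts)
  for (r in seq_len(n_starts)) {
    ini <- fma_init(Y, spec)
    run <- tryCatch(
      fma_em(Y, spec, ini$par, ini$pw, max_iter = init_iter, tol = 1e-4,
             inner_maxit = 25),
      error = function(e) NULL)
    stage1[[r]] <- run
  }
  lls <- vapply(stage1, function(r) if (is.null(r)) -Inf else r$loglik,
                numeric(1))
  if (all(!is.finite(lls))) {
    stop("no EM start converged; check the data scale and spec")
  }
  keep <- order(lls, decreasing = TRUE)[seq_len(n_final)]
  # stage 2: run the best starts to convergence
  stage2 <- lapply(keep, function(r) {
    if (!is.finite(lls[r])) return(NULL)
    tryCatch(
      fma_em(Y, spec, stage1[[r]]$par, stage1[[r]]$pw, max_iter = max_iter,
             tol = tol),
      error = function(e) NULL)
  })
  ll2 <- vapply(stage2, function(r) if (is.null(r)) -Inf else r$loglik,
                numeric(1))
  if (all(!is.finite(ll2))) stop("no final-stage EM run converged")
  best <- stage2[[which.max(ll2)]]
  if (any(diff(best$ll_trace) < -1e-6)) {
    warning("EM loglikelihood decreased during iteration; ",
            "result may be unreliable")
  }
  if (best$floored) {
    warning("mixing weight hit the 1/(2N) floor: class may be empty")
  }
  prm <- fma_map(spec, best$par)
  dimnames(prm$lambda) <- dimnames(prm$nu) <-
    list(c("inconsistent", "consistent"), spec$items)
  names(prm$psi) <- spec$items
  names(prm$alpha) <- names(prm$phi) <- c("inconsistent", "consistent")
  structure(list(
    spec = spec,
    parameters = c(prm, list(mixing_weight = best$pw)),
    par = best$par,
    loglik = best$loglik,
    n_free_parameters = spec$n_free,
    posteriors = best$posteriors,
    entropy = entropy_index(best$posteriors),
    n_starts_run = n_starts,
    best_loglik_replications = sum(is.finite(ll2) &
                                     max(ll2) - ll2 < 0.01),
    ll_trace = best$ll_trace,
    converged = best$converged,
    n = n
  ), class = "fma_fit")
}

#' Standardized within-class loadings of a fitted factor mixture
#'
#' @param fit An `fma_fit`.
#' @return 2 x p matrix of standardized loadings
#'   `lambda * sqrt(phi) / sqrt(lambda^2 phi + psi)`.
#' @export
standardized_loadings <- function(fit) {
  prm <- fit$parameters
  out <- prm$lambda
  for (k in 1:2) {
    v <- prm$lambda[k, ]^2 * prm$phi[k] + prm$psi
    out[k, ] <- prm$lambda[k, ] * sqrt(prm$phi[k]) / sqrt(v)
  }
  out
}

#' Relative entropy index of a posterior classification
#'
#' `E = 1 - sum(-p log p) / (N log K)`, with `0 log 0 := 0`; 1 means
#' perfectly sharp classification, 0 means uninformative posteriors.
#'
#' @param posteriors N x K matrix of class posterior probabilities.
#' @return Scalar in `[0, 1]`.
#' @examples
#' entropy_index(matrix(c(1, 0, 0, 1), 2, byrow = TRUE))  # 1
#' @export
entropy_index <- function(posteriors) {
  posteriors <- as.matrix(posteriors)
  if (any(abs(rowSums(posteriors) - 1) > 1e-8)) {
    stop("posterior rows must sum to 1")
  }
  pl <- posteriors * log(posteriors)
  pl[posteriors == 0] <- 0
  1 + sum(pl) / (nrow(posteriors) * log(ncol(posteriors)))
}

#' Modal class assignment from a fitted factor mixture
#'
#' Respondents are assigned to the class with the larger posterior
#' probability; exact ties are broken toward the consistent class
#' (conservative screening: a respondent is only flagged when the evidence
#' favours inconsistency).
#'
#' @param fit An `fma_fit`, or a posterior matrix with columns
#'   (inconsistent, consistent).
#' @return Object of class `fma_classes`: list with `class` (factor with
#'   levels inconsistent/consistent) and `posterior` (the winning
#'   probability).
#' @export
classify <- function(fit) {
  post <- if (inherits(fit, "fma_fit")) fit$posteriors else as.matrix(fit)
  lab <- ifelse(post[, 1] > post[, 2], "inconsistent", "consistent")
  structure(list(
    class = factor(lab, levels = c("inconsistent", "consistent")),
    posterior = pmax(post[, 1], post[, 2])
  ), class = "fma_classes")
}

#' @export
print.fma_classes <- function(x, ...) {
  print(table(x$class))
  invisible(x)
}

#' Cohen's kappa between two screening classifications
#'
#' Chance-corrected agreement from the 2 x 2 cross-table, with the
#' conventional qualitative bands (none / none-to-slight / fair / moderate /
#' substantial / almost perfect).
#'
#' @param a,b `fma_classes` objects or factors of equal length.
#' @return List with `kappa`, `band`, and the cross-`table`.
#' @examples
#' f <- factor(c("a", "a", "b", "b"))
#' cohen_kappa(f, f)$kappa  # 1
#' @export
cohen_kappa <- function(a, b) {
  if (inherits(a, "fma_classes")) a <- a$class
  if (inherits(b, "fma_classes")) b <- b$class
  if (length(a) != length(b)) stop("classifications must cover the same ",
                                   "respondents")
  tab <- table(a, b)
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  kappa <- if (abs(1 - pe) < 1e-12) 1 else (po - pe) / (1 - pe)
  # small tolerance so exact cut-point values land in their stated band
  eps <- 1e-9
  band <- if (kappa <= 0) "none" else
    if (kappa <= 0.20 + eps) "none to slight" else
      if (kappa <= 0.40 + eps) "fair" else
        if (kappa <= 0.60 + eps) "moderate" else
          if (kappa <= 0.80 + eps) "substantial" else "almost perfect"
  list(kappa = kappa, band = band, table = tab)
}

#' Remove inconsistent respondents from a response matrix
#'
#' @param data Response matrix or data frame.
#' @param assignment An `fma_classes` object (or factor) covering all rows.
#' @return The rows assigned to the consistent class, with the removed rows'
#'   identifiers in `attr(, "removed")`.
#' @export
screen_sample <- function(data, assignment) {
  cls <- if (inherits(assignment, "fma_classes")) {
    assignment$class
  } else as.factor(assignment)
  X <- as_response_matrix(data)
  if (length(cls) != nrow(X)) stop("assignment must cover all rows")
  if (is.null(rownames(X))) rownames(X) <- seq_len(nrow(X))
  drop <- cls == "inconsistent"
  out <- X[!drop, , drop = FALSE]
  attr(out, "removed") <- rownames(X)[drop]
  out
}

#' @export
print.fma_fit <- function(x, digits = 3, ...) {
  cat("Constrained factor mixture fit (", x$spec$model, "), n = ", x$n,
      ", ", x$n_free_parameters, " free parameters\n", sep = "")
  cat(sprintf("loglik = %.2f (best loglik replicated by %d final start%s)\n",
              x$loglik, x$best_loglik_replications,
              if (x$best_loglik_replications == 1) "" else "s"))
  cat(sprintf("mixing weight (inconsistent class) = %.3f, entropy = %.2f\n",
              x$parameters$mixing_weight, x$entropy))
  invisible(x)
}

#' @export
summary.fma_fit <- function(object, ...) {
  cls <- classify(object)
  structure(list(fit = object, classes = table(cls$class),
                 std_loadings = standardized_loadings(object)),
            class = "summary.fma_fit")
}

#' @export
print.summary.fma_fit <- function(x, digits = 3, ...) {
  print(x$fit)
  cat("\nModal classification:\n")
  print(x$classes)
  cat("\nStandardized loadings:\n")
  print(round(x$std_loadings, digits))
  cat("\nIntercepts:\n")
  print(round(x$fit$parameters$nu, digits))
  invisible(x)
}

#' @export
logLik.fma_fit <- function(object, ...) {
  structure(object$loglik, df = object$n_free_parameters,
            nobs = object$n, class = "logLik")
}

#' @export
coef.fma_fit <- function(object, ...) object$parameters

#' @export
predict.fma_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$posteriors)
  Y <- as_response_matrix(newdata)
  prm <- object$parameters
  ld <- fma_logdens(Y, prm)
  lp <- sweep(ld, 2, log(c(prm$mixing_weight, 1 - prm$mixing_weight)), "+")
  post <- exp(lp - row_logsumexp(lp))
  colnames(post) <- c("inconsistent", "consistent")
  post
}

#' @export
simulate.fma_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  prm <- object$parameters
  n <- object$n
  out <- vector("list", nsim)
  p <- object$spec$p
  for (s in seq_len(nsim)) {
    k <- ifelse(stats::runif(n) < prm$mixing_weight, 1L, 2L)
    f <- stats::rnorm(n, prm$alpha[k], sqrt(prm$phi[k]))
    E <- matrix(stats::rnorm(n * p), n) %*% diag(sqrt(prm$psi), p)
    out[[s]] <- prm$nu[k, , drop = FALSE] +
      f * prm$lambda[k, , drop = FALSE] + E
    colnames(out[[s]]) <- object$spec$items
  }
  if (nsim == 1) out[[1]] else out
}
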