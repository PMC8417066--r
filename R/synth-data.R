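#' Specification of the mixed-worded Likert generator
#'
#' Defines the population from which [generate_responses()] draws: a
#' two-class factor mixture over a balanced mixed-worded scale, with a small
#' planted class of inconsistent respondents whose recoded negative items
#' load with flipped sign. Defaults mirror the Dominican self-esteem study
#' design: 5 positive + 5 recoded-negative items, 4 response categories, an
#' 8\% inconsistent class, and consistent-class standardized loadings in the
#' 0.45-0.78 range.
#'
#' Under the `"arias"` mechanism the unstandardized loadings are the +/-1
#' random-intercept pattern, the classes differ only in factor variance
#' (defaults 0.5 inconsistent, 1 consistent) and the sign flip, and all
#' intercepts are shared. Under the `"steinmann"` mechanism the
#' consistent-class loadings are the `loadings` field, the inconsistent
#' class flips the negative-item signs, and the negative-item intercepts of
#' the inconsistent class are shifted down by one latent standard deviation
#' (`lambda` units), reproducing the lower observed negative-item means of
#' flagged respondents.
#'
#' @param mechanism Which constrained-mixture side generates the data.
#' @param n_pos,n_neg Number of positively / recoded negatively worded items.
#' @param n_categories Number of ordered response categories (>= 2).
#' @param mixing_weight Probability of inconsistent-class membership.
#' @param loadings,intercepts,uniquenesses Per-item consistent-class
#'   unstandardized loadings, intercepts and residual variances.
#' @param class_factor_means,class_factor_variances Length-2 factor mean and
#'   variance (inconsistent, consistent).
#' @param neg_intercept_shift Inconsistent-class shift of negative-item
#'   intercepts in latent-SD units (steinmann mechanism only).
#' @param thresholds List of per-item strictly increasing cut points used to
#'   discretize the continuous responses.
#' @param seed Integer seed.
#' @return Object of class `generator_spec`.
#' @export
generator_spec <- function(mechanism = c("arias", "steinmann"),
                           n_pos = 5, n_neg = 5, n_categories = 4,
                           mixing_weight = 0.08,
                           loadings = NULL, intercepts = NULL,
                           uniquenesses = NULL,
                           class_factor_means = NULL,
                           class_factor_variances = NULL,
                           neg_intercept_shift = -1,
                           thresholds = NULL, seed = 1L) {
  mechanism <- match.arg(mechanism)
  p <- n_pos + n_neg
  if (n_neg == 0) {
    stop("classes not identifiable without negatively worded items")
  }
  if (n_categories < 2) stop("n_categories must be at least 2")
  if (mixing_weight < 0 || mixing_weight > 1) {
    stop("mixing_weight must be in [0, 1]")
  }
  # Defaults emulate the study's consistent-class standardized solution.
  std_default <- function(k) {
    base <- if (mechanism == "arias") {
      c(0.74, 0.78, 0.67, 0.65, 0.56, 0.49, 0.60, 0.45, 0.59, 0.50)
    } else {
      c(0.50, 0.65, 0.60, 0.75, 0.60, 0.45, 0.68, 0.51, 0.73, 0.52)
    }
    rep_len(c(rep_len(base[1:5], n_pos), rep_len(base[6:10], n_neg)), k)
  }
  nu_default <- function(k) {
    base <- if (mechanism == "arias") {
      c(3.74, 3.66, 3.49, 3.42, 3.26, 3.21, 3.52, 2.89, 3.40, 3.29)
    } else {
      c(3.78, 3.70, 3.54, 3.47, 3.31, 3.30, 3.66, 2.95, 3.49, 3.35)
    }
    c(rep_len(base[1:5], n_pos), rep_len(base[6:10], n_neg))
  }
  std <- std_default(p)
  if (is.null(class_factor_variances)) {
    class_factor_variances <- if (mechanism == "arias") c(0.5, 1) else c(1, 1)
  }
  if (is.null(class_factor_means)) class_factor_means <- c(0, 0)
  if (is.null(loadings)) {
    loadings <- if (mechanism == "arias") rep(1, p) else std
  }
  if (is.null(uniquenesses)) {
    # residual variance completing a unit-variance consistent-class item
    uniquenesses <- loadings^2 * class_factor_variances[2] *
      (1 / std^2 - 1)
  }
  if (is.null(intercepts)) intercepts <- nu_default(p)
  if (length(loadings) != p || length(intercepts) != p ||
      length(uniquenesses) != p) {
    stop("loadings, intercepts and uniquenesses must have length ", p)
  }
  if (any(uniquenesses <= 0)) stop("uniquenesses must be positive")
  if (is.null(thresholds)) {
    thresholds <- rep(list(seq_len(n_categories - 1) +
                             (4 - n_categories) / 2 + 0.5), p)
    if (n_categories == 4) thresholds <- rep(list(c(1.5, 2.5, 3.5)), p)
  }
  if (!is.list(thresholds)) thresholds <- rep(list(thresholds), p)
  ok <- vapply(thresholds, function(t) {
    length(t) == 0 || all(diff(t) > 0)
  }, logical(1))
  if (!all(ok)) stop("thresholds must be strictly increasing per item")
  items <- c(paste0("p", seq_len(n_pos)), paste0("n", seq_len(n_neg)))
  structure(list(mechanism = mechanism, n_pos = n_pos, n_neg = n_neg,
                 p = p, items = items, n_categories = n_categories,
                 mixing_weight = mixing_weight, loadings = loadings,
                 intercepts = intercepts, uniquenesses = uniquenesses,
                 class_factor_means = class_factor_means,
                 class_factor_variances = class_factor_variances,
                 neg_intercept_shift = neg_intercept_shift,
                 thresholds = thresholds, seed = as.integer(seed)),
            class = "generator_spec")
}

#' Discretize continuous responses by per-item thresholds
#'
#' Value `y` is assigned category `c` iff `y` lies in
#' `(tau[c - 1], tau[c]]`; an empty threshold list yields a single category.
#'
#' @param continuous_matrix Numeric matrix (rows = respondents).
#' @param thresholds List of strictly increasing cut points per column (a
#'   single numeric vector is recycled).
#' @return Integer matrix of categories `1..(length(tau) + 1)`.
#' @examples
#' discretize(cbind(c(-1, -0.1, 0.1, 1)), list(c(-0.674, 0, 0.674)))
#' @export
discretize <- function(continuous_matrix, thresholds) {
  X <- as.matrix(continuous_matrix)
  if (!is.list(thresholds)) thresholds <- rep(list(thresholds), ncol(X))
  if (length(thresholds) != ncol(X)) {
    stop("one threshold vector per column is required")
  }
  out <- matrix(1L, nrow(X), ncol(X), dimnames = dimnames(X))
  for (j in seq_len(ncol(X))) {
    tau <- thresholds[[j]]
    if (length(tau) == 0) next
    if (any(diff(tau) <= 0)) stop("thresholds must be strictly increasing")
    out[, j] <- findInterval(X[, j], tau, left.open = TRUE) + 1L
  }
  out
}

#' Generate mixed-worded Likert responses with a planted inconsistent class
#'
#' Each respondent is drawn into the inconsistent class with probability
#' `mixing_weight`; continuous responses follow
#' `y = nu_k + lambda_k f + e` with `f ~ N(alpha_k, phi_k)` and
#' `e ~ N(0, psi)`, where the inconsistent class's negative-item loadings
#' have flipped sign (see [generator_spec()] for how the two mechanisms
#' differ); values are then cut into ordered categories.
#'
#' @param spec A [generator_spec()].
#' @param n Number of respondents.
#' @param mechanism Override of the spec's mechanism.
#' @param continuous If `TRUE`, skip discretization (for clean
#'   parameter-recovery experiments on the mixture itself).
#' @return Object of class `wordfx_sim`: list with `responses` (matrix),
#'   `true_class` (factor), `latent_scores`, and the `spec`.
#' @examples
#' sim <- generate_responses(generator_spec(seed = 42), n = 100)
#' table(sim$true_class)
#' @export
generate_responses <- function(spec, n,
                               mechanism = spec$mechanism,
                               continuous = FALSE) {
  stopifnot(inherits(spec, "generator_spec"), n >= 1)
  mechanism <- match.arg(mechanism, c("arias", "steinmann"))
  p <- spec$p
  pos <- seq_len(spec$n_pos)
  neg <- spec$n_pos + seq_len(spec$n_neg)
  set.seed(spec$seed)
  lam <- matrix(rep(spec$loadings, each = 2), 2, p)
  lam[1, neg] <- -lam[1, neg]
  nu <- matrix(rep(spec$intercepts, each = 2), 2, p)
  if (mechanism == "steinmann") {
    nu[1, neg] <- nu[1, neg] +
      spec$neg_intercept_shift * abs(lam[1, neg]) *
        sqrt(spec$class_factor_variances[2])
  }
  k <- ifelse(stats::runif(n) < spec$mixing_weight, 1L, 2L)
  f <- stats::rnorm(n, spec$class_factor_means[k],
                    sqrt(spec$class_factor_variances[k]))
  E <- matrix(stats::rnorm(n * p), n) %*% diag(sqrt(spec$uniquenesses), p)
  Y <- nu[k, , drop = FALSE] + f * lam[k, , drop = FALSE] + E
  colnames(Y) <- spec$items
  if (!continuous) Y <- discretize(Y, spec$thresholds)
  structure(list(
    responses = Y,
    true_class = factor(c("inconsistent", "consistent")[k],
                        levels = c("inconsistent", "consistent")),
    latent_scores = f,
    polarity = stats::setNames(rep(c("positive", "negative"),
                                   c(spec$n_pos, spec$n_neg)), spec$items),
    spec = spec
  ), class = "wordfx_sim")
}

#' @export
print.wordfx_sim <- function(x, ...) {
  cat("Synthetic mixed-worded responses: ", nrow(x$responses),
      " respondents x ", ncol(x$responses), " items (",
      x$spec$mechanism, " mechanism)\n", sep = "")
  print(table(x$true_class))
  invisible(x)
}

#' Write simulated responses to CSV with a JSON sidecar
#'
#' The CSV holds one row per respondent with item-ID headers and integer
#' cells; the sidecar (`<file>.json`) stores the true class labels, latent
#' scores and the generator settings, so a simulation round-trips through
#' plain text.
#'
#' @param sim A `wordfx_sim`.
#' @param file CSV output path.
#' @return `file`, invisibly.
#' @export
write_responses <- function(sim, file) {
  utils::write.csv(as.data.frame(sim$responses), file, row.names = FALSE)
  side <- sim$spec
  side$thresholds <- lapply(side$thresholds, as.numeric)
  jsonlite::write_json(
    list(true_class = as.character(sim$true_class),
         latent_scores = sim$latent_scores,
         polarity = as.list(sim$polarity),
         spec = unclass(side)),
    paste0(file, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Read simulated responses written by [write_responses()]
#'
#' @param file CSV path (the `<file>.json` sidecar must sit next to it).
#' @return A `wordfx_sim`-like list (the spec is restored from the sidecar).
#' @export
read_responses <- function(file) {
  Y <- as.matrix(utils::read.csv(file, check.names = FALSE))
  storage.mode(Y) <- "integer"
  side <- jsonlite::read_json(paste0(file, ".json"), simplifyVector = TRUE)
  structure(list(
    responses = Y,
    true_class = factor(side$true_class,
                        levels = c("inconsistent", "consistent")),
    latent_scores = side$latent_scores,
    polarity = unlist(side$polarity),
    spec = side$spec
  ), class = "wordfx_sim")
}
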