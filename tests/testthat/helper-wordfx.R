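# Shared simulation helpers for the test suite.

# Ordinal data from a clean one-factor model: p items with common loading,
# discretized at standard-normal quartile thresholds.
sim_one_factor <- function(n, p = 10, lambda = 0.8, seed = 1) {
  set.seed(seed)
  f <- stats::rnorm(n)
  Y <- lambda * matrix(f, n, p) +
    sqrt(1 - lambda^2) * matrix(stats::rnorm(n * p), n)
  discretize(Y, rep(list(stats::qnorm(c(0.25, 0.5, 0.75))), p))
}

# Ordinal data from two correlated factors (first half of the items on
# factor 1, second half on factor 2).
sim_two_factor <- function(n, p = 10, lambda = 0.8, r = 0.3, seed = 1) {
  set.seed(seed)
  f1 <- stats::rnorm(n)
  f2 <- r * f1 + sqrt(1 - r^2) * stats::rnorm(n)
  half <- p %/% 2
  f <- cbind(matrix(f1, n, half), matrix(f2, n, p - half))
  Y <- lambda * f + sqrt(1 - lambda^2) * matrix(stats::rnorm(n * p), n)
  discretize(Y, rep(list(stats::qnorm(c(0.25, 0.5, 0.75))), p))
}

# Population correlation matrix of a one-factor model plus one freed error
# correlation, used for CFA self-consistency tests.
onef_matrix <- function(lambda, theta = 0, pair = NULL) {
  R <- tcrossprod(lambda)
  if (!is.null(pair)) {
    R[pair[1], pair[2]] <- R[pair[1], pair[2]] + theta
    R[pair[2], pair[1]] <- R[pair[1], pair[2]]
  }
  diag(R) <- 1
  R
}

# Polarity map for p items, first `n_pos` positive.
polarity_of <- function(p, n_pos = p %/% 2) {
  stats::setNames(rep(c("positive", "negative"), c(n_pos, p - n_pos)),
                  c(paste0("p", seq_len(n_pos)),
                    paste0("n", seq_len(p - n_pos))))
}
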