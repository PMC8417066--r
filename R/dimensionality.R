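#' Eigenvalues of a correlation matrix
#'
#' Full (non-reduced) eigendecomposition, sorted descending. The eigenvalues
#' of a p-item correlation matrix sum to p.
#'
#' @param matrix Symmetric correlation matrix with unit diagonal.
#' @return Numeric vector of descending eigenvalues.
#' @examples
#' correlation_eigenvalues(diag(10))            # ten 1s
#' @export
correlation_eigenvalues <- function(matrix) {
  if (inherits(matrix, "polychoric")) matrix <- matrix$matrix
  m <- as.matrix(matrix)
  if (nrow(m) != ncol(m) || max(abs(m - t(m))) > 1e-8) {
    stop("input must be a symmetric square matrix")
  }
  sort(eigen(m, symmetric = TRUE, only.values = TRUE)$values,
       decreasing = TRUE)
}

#' Permutation parallel analysis on polychoric correlations
#'
#' Factor-retention procedure for ordinal items: the empirical eigenvalues
#' of the polychoric correlation matrix are compared with the rank-wise mean
#' eigenvalues of `n_sets` artificial datasets, each obtained by
#' independently permuting every item's column of the observed data (which
#' destroys inter-item association while preserving every marginal
#' distribution exactly). Retention follows the sequential mean criterion:
#' factors are retained while the empirical eigenvalue exceeds the mean
#' random eigenvalue of the same rank.
#'
#' @param data Ordinal response matrix or data frame.
#' @param n_sets Number of permutation datasets (the reference analysis used
#'   1000).
#' @param seed Integer seed for the permutations.
#' @param method `"polychoric"` (default) or `"pearson"` (fast mode for
#'   experimentation; not the reference procedure for ordinal data).
#' @return Object of class `parallel_analysis`: `empirical_eigenvalues`,
#'   `mean_random_eigenvalues`, `n_retained`, `n_sets`, `seed`, `method`.
#' @examples
#' sim <- generate_responses(generator_spec(seed = 7, mixing_weight = 0),
#'                           n = 200)
#' pa <- parallel_analysis(sim$responses, n_sets = 20, seed = 1,
#'                         method = "pearson")
#' pa$n_retained
#' @export
parallel_analysis <- function(data, n_sets = 1000, seed = NULL,
                              method = c("polychoric", "pearson")) {
  method <- match.arg(method)
  X <- as_response_matrix(data)
  n <- nrow(X); p <- ncol(X)
  corr_fun <- if (method == "polychoric") {
    function(M) polychoric(M)$matrix
  } else {
    function(M) stats::cor(M)
  }
  emp <- correlation_eigenvalues(corr_fun(X))
  if (!is.null(seed)) set.seed(seed)
  rand <- matrix(0, n_sets, p)
  for (s in seq_len(n_sets)) {
    Xp <- apply(X, 2, sample)
    rand[s, ] <- correlation_eigenvalues(corr_fun(Xp))
  }
  means <- colMeans(rand)
  above <- emp > means
  n_retained <- if (above[1]) {
    run <- which(!above)
    if (length(run) == 0) p else run[1] - 1L
  } else 0L
  structure(list(empirical_eigenvalues = emp,
                 mean_random_eigenvalues = means,
                 n_retained = as.integer(n_retained),
                 n_sets = n_sets, seed = seed, method = method),
            class = "parallel_analysis")
}

#' @export
print.parallel_analysis <- function(x, digits = 2, ...) {
  cat("Parallel analysis (", x$method, ", ", x$n_sets,
      " permutation sets): retain ", x$n_retained, " factor",
      if (x$n_retained != 1) "s", "\n", sep = "")
  print(round(rbind(empirical = x$empirical_eigenvalues,
                    random_mean = x$mean_random_eigenvalues), digits))
  invisible(x)
}

#' Scree data of a parallel analysis
#'
#' @param x A `parallel_analysis`.
#' @return Data frame with `rank`, `empirical`, `random_mean` — both
#'   eigenvalue series, ready for plotting or CSV export.
#' @export
scree_data <- function(x) {
  stopifnot(inherits(x, "parallel_analysis"))
  data.frame(rank = seq_along(x$empirical_eigenvalues),
             empirical = x$empirical_eigenvalues,
             random_mean = x$mean_random_eigenvalues)
}

#' @export
plot.parallel_analysis <- function(x, ...) {
  d <- scree_data(x)
  graphics::plot(d$rank, d$empirical, type = "b", pch = 19,
                 xlab = "Factor rank", ylab = "Eigenvalue", ...)
  graphics::lines(d$rank, d$random_mean, type = "b", lty = 2, pch = 1)
  graphics::legend("topright", c("empirical", "random mean"),
                   lty = c(1, 2), pch = c(19, 1), bty = "n")
  invisible(x)
}
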