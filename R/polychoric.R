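#' Estimate normal thresholds of an ordinal item
#'
#' Two-step polychoric machinery, step one: the threshold separating observed
#' category `c` from `c + 1` is the standard-normal quantile of the cumulative
#' observed proportion through `c`. Categories with zero observed frequency
#' are handled by the `empty` policy: `"merge"` drops the corresponding
#' threshold (the empty category is absorbed by its neighbour, as is done when
#' sparse response options are collapsed before analysis), `"error"` aborts.
#'
#' @param x Integer-coded ordinal vector (categories `1..n_categories`).
#' @param n_categories Number of response categories; defaults to `max(x)`.
#' @param empty Policy for zero-frequency categories.
#' @return Strictly increasing numeric vector of `C - 1` thresholds (fewer if
#'   empty categories were merged).
#' @export
estimate_thresholds <- function(x, n_categories = max(x),
                                empty = c("merge", "error")) {
  empty <- match.arg(empty)
  x <- x[!is.na(x)]
  if (length(x) < 1) stop("at least one observation is required")
  counts <- tabulate(x, nbins = n_categories)
  if (any(counts == 0)) {
    if (empty == "error") {
      stop("categories with zero observed frequency: ",
           paste(which(counts == 0), collapse = ", "))
    }
  }
  if (sum(counts > 0) < 2) {
    stop("item is degenerate: only one observed category")
  }
  cum <- cumsum(counts) / length(x)
  tau <- stats::qnorm(cum[-n_categories])
  tau <- tau[is.finite(tau)]
  tau[!duplicated(tau)]
}

#' Polychoric correlation of one ordinal pair
#'
#' Two-step maximum likelihood: thresholds are fixed at their marginal
#' estimates, then the latent bivariate-normal correlation maximizing the
#' contingency-table likelihood is found by bracketed scalar optimization on
#' `(-0.999, 0.999)`. Perfect association (an empty off-diagonal block of the
#' table) pushes the estimate to the bracket edge; it is then reported as
#' `+/-(1 - epsilon)` with a warning.
#'
#' @param x,y Integer-coded ordinal vectors of equal length.
#' @param epsilon Shrinkage away from `|rho| = 1` for boundary solutions.
#' @return List with `rho`, `thresholds` (list of the two marginal threshold
#'   vectors) and a `converged` flag.
#' @export
polychoric_pair <- function(x, y, epsilon = 1e-3) {
  if (length(x) != length(y)) stop("x and y must have the same length")
  ok <- !(is.na(x) | is.na(y))
  x <- x[ok]; y <- y[ok]
  tx <- estimate_thresholds(x)
  ty <- estimate_thresholds(y)
  tab <- table(factor(x, levels = sort(unique(x))),
               factor(y, levels = sort(unique(y))))
  nll <- function(rho) -polychoric_loglik(tab, tx, ty, rho)
  opt <- stats::optimize(nll, interval = c(-0.999, 0.999), tol = 1e-8)
  rho <- opt$minimum
  converged <- TRUE
  if (abs(rho) > 0.999 - 1e-4) {
    rho <- sign(rho) * (1 - epsilon)
    warning("perfect association: polychoric correlation set to ",
            signif(rho, 4))
    converged <- FALSE
  }
  list(rho = rho, thresholds = list(tx, ty), converged = converged)
}

# Multinomial loglikelihood of an ordinal contingency table under the
# bivariate-normal model with fixed thresholds.
polychoric_loglik <- function(tab, tx, ty, rho) {
  a <- c(-Inf, tx, Inf)
  b <- c(-Inf, ty, Inf)
  nr <- length(a) - 1L; nc <- length(b) - 1L
  hi <- pbvn(rep(a[-1], nc), rep(b[-1], each = nr), rho)
  lo_r <- pbvn(rep(a[-length(a)], nc), rep(b[-1], each = nr), rho)
  lo_c <- pbvn(rep(a[-1], nc), rep(b[-length(b)], each = nr), rho)
  lo_rc <- pbvn(rep(a[-length(a)], nc), rep(b[-length(b)], each = nr), rho)
  pr <- matrix(hi - lo_r - lo_c + lo_rc, nr, nc)
  pr <- pmax(pr, 1e-12)
  sum(tab * log(pr))
}

#' Polychoric correlation matrix
#'
#' Assembles all pairwise polychoric correlations of an ordinal response
#' matrix. An indefinite assembled matrix is repaired to the nearest positive
#' semi-definite correlation matrix by eigenvalue clipping and rescaling; the
#' `smoothed` flag records that repair occurred.
#'
#' @param data Integer-coded response matrix or data frame (rows =
#'   respondents, columns = items).
#' @param empty Policy for zero-frequency categories, see
#'   [estimate_thresholds()].
#' @return Object of class `polychoric`, a list with `matrix` (p x p),
#'   `thresholds` (per item), `smoothed`, and `converged`.
#' @examples
#' sim <- generate_responses(generator_spec(seed = 1), n = 300)
#' pc <- polychoric(sim$responses)
#' round(pc$matrix[1:3, 1:3], 2)
#' @export
polychoric <- function(data, empty = c("merge", "error")) {
  empty <- match.arg(empty)
  data <- as_response_matrix(data)
  p <- ncol(data)
  if (p < 2) stop("at least two items are required")
  items <- colnames(data)
  if (is.null(items)) items <- paste0("item", seq_len(p))
  thresholds <- lapply(seq_len(p), function(i) {
    estimate_thresholds(data[, i], empty = empty)
  })
  names(thresholds) <- items
  R <- diag(p)
  converged <- TRUE
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      pr <- polychoric_pair(data[, i], data[, j])
      R[i, j] <- R[j, i] <- pr$rho
      converged <- converged && pr$converged
    }
  }
  dimnames(R) <- list(items, items)
  rep <- psd_smooth(R)
  structure(list(matrix = rep$matrix, thresholds = thresholds,
                 smoothed = rep$smoothed, converged = converged),
            class = "polychoric")
}

#' @export
print.polychoric <- function(x, digits = 2, ...) {
  cat("Polychoric correlation matrix (", ncol(x$matrix), " items",
      if (x$smoothed) ", PSD-smoothed" else "", ")\n", sep = "")
  print(round(x$matrix, digits))
  invisible(x)
}

#' Read or write a square correlation matrix as CSV
#'
#' The on-disk format has an item-ID header row and first column, matching
#' the packaged printed-matrix fixtures.
#'
#' @param file Path to a CSV file.
#' @return `read_corr_csv()` returns a named square matrix.
#' @export
read_corr_csv <- function(file) {
  df <- utils::read.csv(file, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  if (nrow(m) != ncol(m)) stop("matrix CSV must be square")
  storage.mode(m) <- "double"
  if (max(abs(m - t(m))) > 1e-8) stop("matrix CSV must be symmetric")
  m
}

#' @rdname read_corr_csv
#' @param R Square correlation matrix (or `polychoric` object).
#' @export
write_corr_csv <- function(R, file) {
  if (inherits(R, "polychoric")) R <- R$matrix
  utils::write.csv(as.data.frame(R), file, row.names = TRUE)
  invisible(file)
}
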