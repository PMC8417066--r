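#' @keywords internal
"_PACKAGE"

# Gauss-Legendre nodes/weights on (-1, 1), 20 points; used by pbvn().
.gl20 <- list(
  x = c(-0.9931285991850949, -0.9639719272779138, -0.9122344282513259,
        -0.8391169718222188, -0.7463319064601508, -0.6360536807265150,
        -0.5108670019508271, -0.3737060887154195, -0.2277858511416451,
        -0.0765265211334973,  0.0765265211334973,  0.2277858511416451,
         0.3737060887154195,  0.5108670019508271,  0.6360536807265150,
         0.7463319064601508,  0.8391169718222188,  0.9122344282513259,
         0.9639719272779138,  0.9931285991850949),
  w = c(0.0176140071391521, 0.0406014298003869, 0.0626720483341091,
        0.0832767415767048, 0.1019301198172404, 0.1181945319615184,
        0.1316886384491766, 0.1420961093183820, 0.1491729864726037,
        0.1527533871307258, 0.1527533871307258, 0.1491729864726037,
        0.1420961093183820, 0.1316886384491766, 0.1181945319615184,
        0.1019301198172404, 0.0832767415767048, 0.0626720483341091,
        0.0406014298003869, 0.0176140071391521)
)

#' Standard bivariate normal CDF
#'
#' Computes `P(X <= h, Y <= k)` for a standard bivariate normal vector with
#' correlation `rho`, vectorized over `h` and `k` (a scalar `rho`). The
#' moderate-correlation regime uses Gauss-Legendre quadrature of the
#' Drezner-Wesolowsky single integral; for `|rho| > 0.925` the computation
#' falls back to [mvtnorm::pmvnorm()] elementwise (rare in practice, e.g.
#' near-perfect polychoric associations).
#'
#' @param h,k Numeric vectors of upper integration limits (recycled).
#' @param rho Scalar correlation in `[-1, 1]`.
#' @return Numeric vector of probabilities.
#' @examples
#' pbvn(0, 0, 0.5)   # 1/4 + asin(0.5) / (2 * pi)
#' @export
pbvn <- function(h, k, rho) {
  n <- max(length(h), length(k))
  h <- rep_len(as.numeric(h), n)
  k <- rep_len(as.numeric(k), n)
  stopifnot(length(rho) == 1L, is.finite(rho), rho >= -1, rho <= 1)
  if (rho == 0) return(stats::pnorm(h) * stats::pnorm(k))
  if (rho == 1) return(stats::pnorm(pmin(h, k)))
  if (rho == -1) return(pmax(stats::pnorm(h) + stats::pnorm(k) - 1, 0))
  out <- numeric(n)
  inf_h <- h > 8; inf_k <- k > 8
  ninf <- h < -8 | k < -8
  out[inf_h & !ninf] <- stats::pnorm(k[inf_h & !ninf])
  out[inf_k & !ninf & !inf_h] <- stats::pnorm(h[inf_k & !ninf & !inf_h])
  todo <- !(inf_h | inf_k | ninf)
  if (!any(todo)) return(out)
  hh <- h[todo]; kk <- k[todo]
  if (abs(rho) <= 0.925) {
    # Phi2(h,k,rho) = Phi(h)Phi(k) +
    #   1/(2 pi) * int_0^asin(rho) exp(-(h^2 - 2hk sin t + k^2)/(2 cos^2 t)) dt
    asr <- asin(rho)
    tt <- asr * (.gl20$x + 1) / 2
    sn <- sin(tt)
    hs <- (hh^2 + kk^2) / 2
    hk <- hh * kk
    acc <- numeric(length(hh))
    for (i in seq_along(tt)) {
      acc <- acc + .gl20$w[i] * exp((sn[i] * hk - hs) / (1 - sn[i]^2))
    }
    out[todo] <- stats::pnorm(hh) * stats::pnorm(kk) + acc * asr / (4 * pi)
  } else {
    if (!requireNamespace("mvtnorm", quietly = TRUE)) {
      stop("package 'mvtnorm' is required for |rho| > 0.925")
    }
    cm <- matrix(c(1, rho, rho, 1), 2)
    out[todo] <- vapply(seq_along(hh), function(i) {
      mvtnorm::pmvnorm(upper = c(hh[i], kk[i]), corr = cm)[1]
    }, numeric(1))
  }
  pmin(pmax(out, 0), 1)
}

# Nearest-PSD repair for a correlation matrix: clip eigenvalues at `eps`,
# reconstruct and rescale to unit diagonal.
psd_smooth <- function(R, eps = 1e-6) {
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) >= 0) return(list(matrix = R, smoothed = FALSE))
  v <- pmax(e$values, eps)
  S <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(diag(S))
  S <- S / tcrossprod(d)
  diag(S) <- 1
  dimnames(S) <- dimnames(R)
  list(matrix = (S + t(S)) / 2, smoothed = TRUE)
}

# Validate / normalize an item-polarity vector against a data matrix.
check_polarity <- function(polarity, p, items = NULL) {
  nm <- names(polarity)
  polarity <- match.arg(as.character(polarity), c("positive", "negative"),
                        several.ok = TRUE)
  if (length(polarity) != p) {
    stop("polarity map must name every item (expected ", p, " entries, got ",
         length(polarity), ")")
  }
  names(polarity) <- nm
  polarity
}

# log(sum(exp(x))) row-wise for an n x k matrix.
row_logsumexp <- function(lp) {
  m <- apply(lp, 1, max)
  m + log(rowSums(exp(lp - m)))
}

# Extract a plain numeric matrix from a ResponseMatrix-like input.
as_response_matrix <- function(data) {
  if (is.data.frame(data)) data <- as.matrix(data)
  if (!is.matrix(data) || !is.numeric(data)) {
    stop("responses must be a numeric matrix or data frame")
  }
  data
}
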