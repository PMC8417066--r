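#' Published RSES polychoric correlation matrices
#'
#' Returns one of the three 10 x 10 polychoric correlation matrices of the
#' Dominican Rosenberg Self-Esteem Scale study that this package ships as
#' plain-text fixtures: the total sample (N = 632) and the two screened
#' samples (N = 588, sign-flip screen; N = 582, random-intercept screen).
#' Items are labelled `p1..p5` (positively worded) and `n1..n5` (recoded
#' negatively worded).
#'
#' Two transcription notes: the source prints the total-sample `p3`-`p4`
#' entry as ".052", an evident misprint for 0.52, which is what the fixture
#' encodes; and the source's stated 0.53 average among recoded negative items
#' in the total sample recomputes to 0.52 from the rounded printed entries.
#'
#' @param sample Which matrix: `"total"`, `"steinmann"` (N = 588 screen) or
#'   `"arias"` (N = 582 screen).
#' @return A named list with `matrix` (10 x 10 correlation matrix) and `n`
#'   (the sample size behind the matrix).
#' @examples
#' rses_polychoric("total")$n
#' @export
rses_polychoric <- function(sample = c("total", "steinmann", "arias")) {
  sample <- match.arg(sample)
  file <- system.file("extdata",
                      sprintf("rses_polychoric_%s.csv", sample),
                      package = "wordfx", mustWork = TRUE)
  n <- c(total = 632L, steinmann = 588L, arias = 582L)[[sample]]
  list(matrix = read_corr_csv(file), n = n)
}

#' Item polarity map of the RSES fixtures
#'
#' @return Character vector of length 10 with entries `"positive"` /
#'   `"negative"`, named by item.
#' @export
rses_polarity <- function() {
  stats::setNames(rep(c("positive", "negative"), each = 5),
                  c(paste0("p", 1:5), paste0("n", 1:5)))
}
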