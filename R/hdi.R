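#' Highest density interval of a sample
#'
#' The smallest interval containing a fraction `prob` of the draws: among all
#' contiguous windows of `ceiling(prob * S)` sorted samples, the narrowest
#' one (ties broken by the lowest lower bound).
#'
#' @param x numeric vector of draws (at least 2 finite values).
#' @param prob coverage in (0, 1]; default 0.95.
#' @return Named numeric vector `c(lower, upper)`.
#' @examples
#' hdi(rexp(1000), prob = 0.9)
#' @export
hdi <- function(x, prob = 0.95) {
  if (!is.numeric(prob) || length(prob) != 1 || prob <= 0 || prob > 1)
    stop_input("'prob' must be in (0, 1]")
  x <- x[is.finite(x)]
  S <- length(x)
  if (S < 2) stop_input("need at least 2 finite samples for an HDI")
  xs <- sort(x)
  m <- ceiling(prob * S)
  if (m >= S) return(c(lower = xs[1], upper = xs[S]))
  widths <- xs[m:S] - xs[1:(S - m + 1)]
  i <- which.min(widths)             # first minimum = lowest lower bound
  c(lower = xs[i], upper = xs[i + m - 1])
}
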