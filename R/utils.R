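#' @keywords internal
"_PACKAGE"

## log(sum(exp(x))) without overflow; -Inf-safe
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

## log(mean(exp(x)))
logmeanexp <- function(x) logsumexp(x) - log(length(x))

stop_input <- function(...) stop(..., call. = FALSE)

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

## non-standard evaluation columns used in ggplot2 calls
utils::globalVariables(c("n", "k", "ppd_lo", "ppd_hi", "hdi_lo", "hdi_hi",
                         "mean", "model", "label"))
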