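# Shared small utilities.

#' Equal-tailed credible interval
#'
#' The 2.5-97.5\% (for `level = 0.95`) empirical quantiles of a sample, with
#' linear interpolation between order statistics.
#'
#' @param samples Numeric vector (length >= 1; >= 2 for a meaningful
#'   interval).
#' @param level Credibility level in (0, 1).
#' @return Numeric vector `c(lo, hi)`.
#' @export
credible_interval <- function(samples, level = 0.95) {
  if (length(samples) == 0 || all(is.na(samples)))
    stop("credible_interval: empty sample")
  a <- (1 - level) / 2
  q <- stats::quantile(samples, probs = c(a, 1 - a), names = FALSE,
                       na.rm = TRUE, type = 7)
  c(lo = q[1], hi = q[2])
}

# derive a replicate seed from a master seed with a simple counter scheme,
# kept inside the 32-bit integer range
.derive_seed <- function(seed, counter) {
  as.integer((as.numeric(seed) * 7919 + counter) %% 2147483629)
}
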