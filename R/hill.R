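# Hill dose-response model for the six non-hERG currents: pore-block
# percent-block curves, bounded non-linear least squares, and the
# extrapolation-reliability diagnostic.  Block is handled throughout on the
# 0-100 percent scale; concentrations in nM; pIC50 = -log10(IC50/c0) with
# c0 = 1e9 nM.

#' Hill dose-response parameters
#'
#' @param pIC50 `-log10(IC50 / c0)` with `c0 = 1e9` nM (so `IC50 =
#'   1e9 * 10^-pIC50` nM); bounded to \[-1, 19\].
#' @param h Hill coefficient, bounded to \[0, 10\].
#' @param sigma2 Optional observation variance (percent^2).
#' @param unconstrained Flag set by [fit_hill_nls()] when the data cannot
#'   constrain the curve (too little block observed).
#' @return A `hill_params` list.
#' @export
hill_params <- function(pIC50, h, sigma2 = NULL, unconstrained = FALSE) {
  bounds <- .default_config()$hill_bounds
  if (pIC50 < bounds$pIC50[1] - 1e-9 || pIC50 > bounds$pIC50[2] + 1e-9)
    stop("pIC50 outside [", bounds$pIC50[1], ", ", bounds$pIC50[2], "]")
  if (h < bounds$h[1] - 1e-9 || h > bounds$h[2] + 1e-9)
    stop("h outside [", bounds$h[1], ", ", bounds$h[2], "]")
  if (!is.null(sigma2) && sigma2 <= 0) stop("sigma2 must be > 0")
  structure(list(pIC50 = pIC50, h = h, sigma2 = sigma2,
                 unconstrained = unconstrained),
            class = "hill_params")
}

#' IC50 (nM) of a Hill parameterization
#' @param hp [hill_params()] or a pIC50 value.
#' @export
hill_ic50 <- function(hp) {
  p <- if (inherits(hp, "hill_params")) hp$pIC50 else hp
  1e9 * 10^(-p)
}

#' Percent block of the Hill equation
#'
#' `100 * D^h / (D^h + IC50^h)`; 0 at `D = 0`, 50 at `D = IC50`, monotone
#' nondecreasing in both `D` and `pIC50` for `h > 0`.
#'
#' @param hp [hill_params()].
#' @param D Concentration (nM), vectorized, `>= 0`.
#' @return Percent block in \[0, 100\].
#' @export
hill_block <- function(hp, D) {
  if (any(D < 0)) stop("concentration must be >= 0")
  ic50 <- hill_ic50(hp)
  out <- numeric(length(D))
  pos <- D > 0
  # D^h/(D^h+IC50^h) = logistic(h * log(D/IC50)), stable across magnitudes
  out[pos] <- 100 * stats::plogis(hp$h * (log(D[pos]) - log(ic50)))
  if (hp$h == 0) out[pos] <- 50 # degenerate flat curve
  out
}

#' Dose-response points
#'
#' @param conc Concentrations (nM), > 0.
#' @param block Observed percent block (values slightly outside \[0, 100\]
#'   are legitimate measurement noise).
#' @param replicate Optional replicate ids.
#' @return data.frame with columns `conc`, `block`, `replicate`.
#' @export
dose_response_points <- function(conc, block, replicate = NULL) {
  stopifnot(length(conc) == length(block), all(conc > 0),
            all(is.finite(block)))
  if (is.null(replicate)) replicate <- seq_along(conc)
  data.frame(conc = conc, block = block, replicate = replicate)
}

#' Bounded non-linear least-squares Hill fit
#'
#' Deterministic multi-start bounded optimization of (pIC50, h) minimizing
#' the residual sum of squares on the percent-block scale.  When the maximum
#' per-concentration mean block falls below `min_block` (default 20%), the
#' data cannot bracket the IC50 and the fit is flagged `unconstrained`
#' (degenerate all-zero data returns a boundary fit with the flag set).
#'
#' @param points data.frame from [dose_response_points()].
#' @param bounds List with `pIC50` and `h` ranges; default from the model
#'   configuration.
#' @param min_block Reliability threshold (percent) on the maximum observed
#'   mean block.
#' @return A [hill_params()] with `sigma2` set to the residual variance
#'   (RSS / (n - 2), or RSS / n when n <= 2).
#' @export
fit_hill_nls <- function(points, bounds = .default_config()$hill_bounds,
                         min_block = 20) {
  if (length(unique(points$conc)) < 2)
    stop("need at least 2 distinct concentrations")
  rss <- function(par) {
    hp <- list(pIC50 = par[1], h = par[2])
    class(hp) <- "hill_params"
    sum((points$block - hill_block(hp, points$conc))^2)
  }
  starts <- expand.grid(pIC50 = seq(bounds$pIC50[1] + 0.5,
                                    min(bounds$pIC50[2], 12), by = 1.5),
                        h = c(0.5, 1, 2))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    res <- stats::optim(as.numeric(starts[i, ]), rss, method = "L-BFGS-B",
                        lower = c(bounds$pIC50[1], bounds$h[1]),
                        upper = c(bounds$pIC50[2], bounds$h[2]))
    if (is.null(best) || res$value < best$value) best <- res
  }
  n <- nrow(points)
  sigma2 <- best$value / max(n - 2, 1)
  mean_by_conc <- tapply(points$block, points$conc, mean)
  unconstrained <- max(mean_by_conc) < min_block
  hill_params(best$par[1], best$par[2],
              sigma2 = max(sigma2, 1e-8), unconstrained = unconstrained)
}

#' Credible interval of percent block at a concentration
#'
#' Evaluates the Hill equation for every saved posterior draw and returns the
#' equal-tailed interval.
#'
#' @param chain An [mcmc_hill()] chain.
#' @param D Concentration (nM).
#' @param level Interval level.
#' @return `c(lo, hi)` in percent.
#' @export
block_ci <- function(chain, D, level = 0.95) {
  stopifnot(nrow(chain$draws) >= 1)
  blocks <- 100 * stats::plogis(chain$draws[, "h"] *
    (log(D) - log(1e9 * 10^(-chain$draws[, "pIC50"]))))
  credible_interval(blocks, level)
}

#' Dose-response extrapolation uncertainty
#'
#' Width of the posterior 95% block interval at multiples of the highest
#' tested concentration Chigh, plus the reliability flag: extrapolation is
#' deemed reliable only when the observed mean block at 1x Chigh exceeds the
#' threshold (default 60%), the regime in which the dose-response curve is
#' constrained enough to predict beyond the tested range.
#'
#' @param chain An [mcmc_hill()] chain.
#' @param Chigh Highest tested concentration (nM), > 0.
#' @param multiples Concentration multiples to evaluate.
#' @param points Optional dose-response data; the mean observed block at the
#'   concentration closest to Chigh feeds the flag.  Without data the flag is
#'   `NA`.
#' @param threshold Percent block required for the `reliable` flag.
#' @param level Interval level.
#' @return List with `multiples`, `width` (percent per multiple),
#'   `observed_block` (mean at Chigh or NA), `reliable`.
#' @export
extrapolation_uncertainty <- function(chain, Chigh, multiples = c(1, 2, 3, 10),
                                      points = NULL, threshold = 60,
                                      level = 0.95) {
  stopifnot(Chigh > 0)
  width <- vapply(multiples, function(m) {
    ci <- block_ci(chain, m * Chigh, level)
    unname(ci[2] - ci[1])
  }, numeric(1))
  observed <- NA_real_
  if (!is.null(points)) {
    near <- which.min(abs(log(points$conc) - log(Chigh)))
    observed <- mean(points$block[points$conc == points$conc[near]])
  }
  list(multiples = multiples, width = stats::setNames(width, multiples),
       observed_block = observed,
       reliable = if (is.na(observed)) NA else observed > threshold)
}

#' Published Hill parameters for the CiPA training compounds
#'
#' Optimal NLS values and 95\% interval bounds per drug-current pair
#' (FDA CiPA initiative / companion publications); `NA` rows mark pairs with
#' no measurable block, which carry a null effect (0\% block at all
#' concentrations).
#'
#' @return data.frame.
#' @export
hill_parameter_table <- function() {
  utils::read.csv(system.file("extdata", "hill_parameters.csv",
                              package = "qnetuq"))
}
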