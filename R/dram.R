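# Delayed-rejection adaptive Metropolis (DRAM) sampling of Hill dose-response
# parameters (pIC50, h) with a conjugate inverse-gamma Gibbs update for the
# observation variance sigma^2.
#
# Model: observed percent block ~ Normal(hill_block(pIC50, h, D), sigma^2),
# uniform prior on (pIC50, h) over the fitting box, inverse-gamma prior on
# sigma^2 (vague, centred on the NLS residual variance).

.hill_rss <- function(par, points) {
  pred <- 100 * stats::plogis(par[2] * (log(points$conc) -
                                        log(1e9 * 10^(-par[1]))))
  if (par[2] == 0) pred <- rep(50, nrow(points))
  sum((points$block - pred)^2)
}

#' DRAM posterior sampling of Hill parameters
#'
#' Adaptive Metropolis in (pIC50, h) with one delayed-rejection stage and a
#' Gibbs step for sigma^2; burn-in and thinning are applied before saving
#' `n_saved` draws.  The chain is deterministic given `seed`.
#'
#' @param points data.frame from [dose_response_points()].
#' @param init A [hill_params()] to start from (typically the
#'   [fit_hill_nls()] optimum); its `sigma2` centres the variance prior.
#' @param n_saved Number of saved draws (after burn-in and thinning).
#' @param seed Integer seed.
#' @param burn_in Burn-in iterations.
#' @param thin Thinning interval.
#' @param adapt_every Adaptation interval for the proposal covariance.
#' @param dr_scale Scale factor of the narrower delayed-rejection proposal.
#' @param prior_weight Weight (fraction of n observations) of the
#'   inverse-gamma prior on sigma^2.
#' @param bounds Box for (pIC50, h); default from the model configuration.
#' @return An `mcmc_chain`: list with `draws` (n_saved x 2 matrix, columns
#'   `pIC50`, `h`), `sigma2` (trace), `acceptance`, `seed`, `n_saved`.
#' @export
mcmc_hill <- function(points, init, n_saved = 2000, seed = 1,
                      burn_in = 10000, thin = 5, adapt_every = 100,
                      dr_scale = 0.25, prior_weight = 0.1,
                      bounds = .default_config()$hill_bounds) {
  stopifnot(inherits(init, "hill_params"), n_saved >= 1)
  set.seed(seed)
  lo <- c(bounds$pIC50[1], bounds$h[1])
  up <- c(bounds$pIC50[2], bounds$h[2])
  n <- nrow(points)
  s2_nls <- if (!is.null(init$sigma2)) init$sigma2 else 25
  a0 <- 0.5 * n * prior_weight
  b0 <- a0 * s2_nls

  n_iter <- burn_in + n_saved * thin
  x <- pmin(pmax(c(init$pIC50, init$h), lo), up)
  rss_x <- .hill_rss(x, points)
  sigma2 <- max(s2_nls, 1e-6)

  # proposal covariance: start from a modest diagonal in (pIC50, h); a global
  # scale lambda is adapted toward a target acceptance rate alongside the
  # history-covariance adaptation
  S <- diag(c(0.25, 0.1))
  lambda <- 1
  target_acc <- 0.35
  chol_S0 <- chol(S)
  chol_S <- lambda * chol_S0
  sd_fac <- 2.4^2 / 2
  eps <- 1e-10

  in_box <- function(p) all(p >= lo) && all(p <= up)
  log_post <- function(rss, s2) -rss / (2 * s2)

  hist_x <- matrix(NA_real_, n_iter, 2)
  draws <- matrix(NA_real_, n_saved, 2,
                  dimnames = list(NULL, c("pIC50", "h")))
  s2_trace <- numeric(n_saved)
  acc <- 0L
  acc_window <- 0L
  kept <- 0L

  for (it in seq_len(n_iter)) {
    # --- sigma^2 Gibbs update from its inverse-gamma full conditional ---
    sigma2 <- 1 / stats::rgamma(1, shape = a0 + n / 2,
                                rate = b0 + rss_x / 2)
    # --- stage 1 proposal ---
    y1 <- x + drop(stats::rnorm(2) %*% chol_S)
    accepted <- FALSE
    if (in_box(y1)) {
      rss_y1 <- .hill_rss(y1, points)
      a1 <- exp(log_post(rss_y1, sigma2) - log_post(rss_x, sigma2))
      if (stats::runif(1) < a1) {
        x <- y1; rss_x <- rss_y1; accepted <- TRUE
      }
    } else {
      rss_y1 <- Inf
      a1 <- 0
    }
    # --- delayed rejection stage ---
    if (!accepted) {
      y2 <- x + drop(stats::rnorm(2) %*% (dr_scale * chol_S))
      if (in_box(y2)) {
        rss_y2 <- .hill_rss(y2, points)
        # alpha(y2, y1)
        a12 <- if (is.finite(rss_y1))
          min(1, exp(log_post(rss_y1, sigma2) - log_post(rss_y2, sigma2)))
        else 0
        Sinv <- chol2inv(chol_S)
        q_num <- exp(-0.5 * drop(t(y1 - y2) %*% Sinv %*% (y1 - y2)))
        q_den <- exp(-0.5 * drop(t(y1 - x) %*% Sinv %*% (y1 - x)))
        num <- exp(log_post(rss_y2, sigma2) - log_post(rss_x, sigma2)) *
          q_num * (1 - a12)
        den <- q_den * (1 - min(1, a1))
        if (den > 0 && stats::runif(1) < num / den) {
          x <- y2; rss_x <- rss_y2; accepted <- TRUE
        }
      }
    }
    if (accepted) {
      acc_window <- acc_window + 1L
      if (it > burn_in) acc <- acc + 1L
    }
    hist_x[it, ] <- x
    # --- adapt proposal covariance and global scale ---
    if (it %% adapt_every == 0) {
      lambda <- lambda *
        exp((acc_window / adapt_every - target_acc) / sqrt(it / adapt_every))
      lambda <- min(max(lambda, 1e-3), 1e3)
      acc_window <- 0L
      if (it >= 200) {
        Ch <- stats::cov(hist_x[seq_len(it), , drop = FALSE])
        ch <- tryCatch(chol(sd_fac * Ch + eps * diag(2)),
                       error = function(e) NULL)
        if (!is.null(ch)) chol_S0 <- ch
      }
      chol_S <- lambda * chol_S0
    }
    if (it > burn_in && (it - burn_in) %% thin == 0) {
      kept <- kept + 1L
      draws[kept, ] <- x
      s2_trace[kept] <- sigma2
    }
  }
  rate <- acc / (n_iter - burn_in)
  if (rate < 0.05 || rate > 0.7)
    warning("mcmc_hill: acceptance rate ", round(rate, 3),
            " outside [0.05, 0.7] after adaptation")
  structure(list(draws = draws, sigma2 = s2_trace, acceptance = rate,
                 seed = seed, n_saved = n_saved),
            class = "mcmc_chain")
}
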