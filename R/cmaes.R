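# Covariance Matrix Adaptation Evolution Strategy (CMA-ES) with box
# constraints.  (mu/mu_w, lambda) selection, cumulative step-size adaptation
# and rank-1 + rank-mu covariance updates, following Hansen's reference
# formulation.  Out-of-box samples are evaluated at their projection onto the
# box with a quadratic distance penalty, which keeps the objective defined
# everywhere while steering the search back inside.

#' Minimize a function with CMA-ES under box constraints
#'
#' @param fn Objective; receives a numeric vector, returns a scalar
#'   (non-finite values are treated as very bad, so `Inf` is a safe failure
#'   signal).
#' @param x0 Start point (also the initial distribution mean).
#' @param lower,upper Box bounds (finite, same length as `x0`).
#' @param sigma Initial step size; default 1/4 of the mean box width.
#' @param lambda Population size; default `4 + floor(3 log d)`.
#' @param maxit Maximum number of generations.
#' @param stop_tol Stop when the step size times the largest covariance scale
#'   falls below this.
#' @param seed Integer seed; the run is deterministic given it.
#' @return List with `par`, `value`, `counts` (evaluations), `convergence`
#'   (0 = tolerance reached, 1 = generation cap).
#' @export
cma_es <- function(fn, x0, lower, upper, sigma = NULL, lambda = NULL,
                   maxit = 300, stop_tol = 1e-10, seed = 1) {
  d <- length(x0)
  stopifnot(length(lower) == d, length(upper) == d,
            all(is.finite(lower)), all(is.finite(upper)),
            all(upper > lower))
  set.seed(seed)
  width <- upper - lower
  if (is.null(sigma)) sigma <- mean(width) / 4
  if (is.null(lambda)) lambda <- 4 + floor(3 * log(d))
  mu <- floor(lambda / 2)
  w <- log(mu + 0.5) - log(seq_len(mu))
  w <- w / sum(w)
  mueff <- 1 / sum(w^2)
  cc <- (4 + mueff / d) / (d + 4 + 2 * mueff / d)
  cs <- (mueff + 2) / (d + mueff + 5)
  c1 <- 2 / ((d + 1.3)^2 + mueff)
  cmu <- min(1 - c1, 2 * (mueff - 2 + 1 / mueff) / ((d + 2)^2 + mueff))
  damps <- 1 + 2 * max(0, sqrt((mueff - 1) / (d + 1)) - 1) + cs
  chiN <- sqrt(d) * (1 - 1 / (4 * d) + 1 / (21 * d^2))

  xmean <- pmin(pmax(x0, lower), upper)
  ps <- pc <- numeric(d)
  C <- diag(d)
  best_x <- xmean
  best_f <- fn(xmean)
  if (!is.finite(best_f)) best_f <- Inf
  evals <- 1L
  eig <- eigen(C, symmetric = TRUE)
  invsqrtC <- diag(d)
  B <- diag(d); D <- rep(1, d)

  penal_fn <- function(x) {
    xc <- pmin(pmax(x, lower), upper)
    pen <- sum(((x - xc) / width)^2)
    f <- fn(xc)
    if (!is.finite(f)) f <- 1e12
    f + 1e6 * pen
  }

  conv <- 1L
  for (g in seq_len(maxit)) {
    Z <- matrix(stats::rnorm(d * lambda), d, lambda)
    Y <- B %*% (D * Z)
    X <- xmean + sigma * Y
    f <- apply(X, 2, penal_fn)
    evals <- evals + lambda
    ord <- order(f)
    if (f[ord[1]] < best_f) {
      best_f <- f[ord[1]]
      best_x <- pmin(pmax(X[, ord[1]], lower), upper)
    }
    sel <- ord[seq_len(mu)]
    yw <- drop(Y[, sel, drop = FALSE] %*% w)
    xmean <- xmean + sigma * yw
    ps <- (1 - cs) * ps + sqrt(cs * (2 - cs) * mueff) * drop(invsqrtC %*% yw)
    hsig <- as.numeric(sqrt(sum(ps^2)) /
      sqrt(1 - (1 - cs)^(2 * g)) / chiN < 1.4 + 2 / (d + 1))
    pc <- (1 - cc) * pc + hsig * sqrt(cc * (2 - cc) * mueff) * yw
    Ymu <- Y[, sel, drop = FALSE]
    C <- (1 - c1 - cmu) * C +
      c1 * (tcrossprod(pc) + (1 - hsig) * cc * (2 - cc) * C) +
      cmu * Ymu %*% (w * t(Ymu))
    sigma <- sigma * exp((cs / damps) * (sqrt(sum(ps^2)) / chiN - 1))
    C <- (C + t(C)) / 2
    eig <- eigen(C, symmetric = TRUE)
    Dg <- eig$values
    if (any(Dg <= 0)) Dg <- pmax(Dg, 1e-14)
    B <- eig$vectors
    D <- sqrt(Dg)
    invsqrtC <- B %*% (t(B) / D)
    if (sigma * max(D) < stop_tol) { conv <- 0L; break }
    if (!is.finite(sigma) || sigma > 1e6 * mean(width)) break
  }
  list(par = best_x, value = best_f, counts = evals, convergence = conv)
}
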