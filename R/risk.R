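# Ordinal TdP risk classification from qNet distributions: proportional-odds
# (cumulative-logit) regression by maximum likelihood with analytic gradient,
# leave-one-drug-out cross-validation, and the current-knockout sensitivity
# analysis.

#' TdP risk labels of the CiPA training compounds
#'
#' @return data.frame with `drug`, `risk`, `category` (0 = Low,
#'   1 = Intermediate, 2 = High).
#' @export
risk_labels <- function() {
  utils::read.csv(system.file("extdata", "tdp_risk_labels.csv",
                              package = "qnetuq"))
}

# negative log-likelihood and gradient of the cumulative-logit model
# logit P(Y <= k) = zeta_k - beta * q, categories 0..K-1, K-1 intercepts.
# parameters: p = (zeta_1, log(zeta_2 - zeta_1), ..., beta) to keep the
# intercepts ordered.
.po_unpack <- function(p, K) {
  nz <- K - 1
  zeta <- numeric(nz)
  zeta[1] <- p[1]
  if (nz > 1) zeta[2:nz] <- zeta[1] + cumsum(exp(p[2:nz]))
  list(zeta = zeta, beta = p[K])
}

.po_nll <- function(p, q, y, K) {
  u <- .po_unpack(p, K)
  eta <- u$beta * q
  cum <- cbind(0, stats::plogis(outer(-eta, u$zeta, `+`)), 1)
  pr <- cum[cbind(seq_along(y), y + 2)] - cum[cbind(seq_along(y), y + 1)]
  -sum(log(pmax(pr, 1e-300)))
}

.po_grad <- function(p, q, y, K) {
  u <- .po_unpack(p, K)
  nz <- K - 1
  eta <- u$beta * q
  G <- stats::plogis(outer(-eta, u$zeta, `+`)) # n x nz cumulative probs
  g <- G * (1 - G)                             # logistic densities
  cum <- cbind(0, G, 1)
  gden <- cbind(0, g, 0)
  pr <- pmax(cum[cbind(seq_along(y), y + 2)] - cum[cbind(seq_along(y), y + 1)],
             1e-300)
  # pr_i = F(zeta_{y+1} - eta) - F(zeta_y - eta) with F(zeta_0) = 0 and
  # F(zeta_K) = 1, so d pr/d zeta_k = f(zeta_k - eta) ([k == y+1] - [k == y])
  dz <- matrix(0, length(y), nz)
  for (k in seq_len(nz)) {
    dz[, k] <- g[, k] * ((y + 1) == k) - g[, k] * (y == k)
  }
  dbeta <- -(gden[cbind(seq_along(y), y + 2)] -
             gden[cbind(seq_along(y), y + 1)]) * q
  w <- 1 / pr
  gz <- -colSums(dz * w)
  gb <- -sum(dbeta * w)
  # chain rule to the ordered parameterization
  J <- matrix(0, nz, nz)
  J[, 1] <- 1
  if (nz > 1) for (k in 2:nz) for (l in 2:k) J[k, l] <- exp(p[l])
  c(drop(t(J) %*% gz), gb)
}

#' Fit a proportional-odds model on (qNet, category) samples
#'
#' Maximum-likelihood cumulative-logit fit with analytic gradient (BFGS,
#' relative tolerance 1e-10, generous iteration cap).  Quasi-complete
#' separation is handled by cap-and-warn: the optimizer stops at the caps and
#' the fit is returned with a warning rather than penalized.
#'
#' @param qnet Numeric qNet values (the single predictor).
#' @param category Integer categories 0..K-1 (0 = Low risk ... 2 = High).
#' @param tol Relative convergence tolerance.
#' @param maxit Iteration cap.
#' @return An `ordinal_model`: list with `zeta` (ordered intercepts), `beta`
#'   (slope on qNet), `K`, `converged`, `value` (final NLL).
#' @export
fit_proportional_odds <- function(qnet, category, tol = 1e-10, maxit = 1e6) {
  stopifnot(length(qnet) == length(category))
  cats <- sort(unique(category))
  K <- length(cats)
  if (K < 2) stop("degenerate_training_set: a single category is present")
  if (!all(cats == seq_len(K) - 1))
    stop("categories must be coded 0..K-1 and all present")
  y <- as.integer(category)
  # scale qNet for optimization stability; undo afterwards
  sc <- stats::sd(qnet)
  if (!is.finite(sc) || sc == 0) sc <- 1
  qs <- qnet / sc
  cum0 <- pmin(pmax(cumsum(tabulate(y + 1, K) / length(y))[seq_len(K - 1)],
                    0.01), 0.99)
  zeta0 <- stats::qlogis(cum0)
  zeta0 <- cummax(zeta0 + seq_len(K - 1) * 1e-3) # strictly increasing
  p0 <- c(zeta0[1],
          if (K > 2) log(diff(zeta0)) else NULL,
          0)
  res <- stats::optim(p0, .po_nll, gr = .po_grad, q = qs, y = y, K = K,
                      method = "BFGS",
                      control = list(reltol = tol, maxit = maxit))
  u <- .po_unpack(res$par, K)
  if (res$convergence != 0)
    warning("proportional-odds fit stopped at iteration/parameter caps ",
            "(possible quasi-complete separation)")
  structure(list(zeta = u$zeta, beta = u$beta / sc, K = K,
                 converged = res$convergence == 0, value = res$value),
            class = "ordinal_model")
}

#' Predict category probabilities for qNet values
#'
#' Cumulative-logit probabilities with deterministic argmax assignment; ties
#' resolve to the lower category.
#'
#' @param model An [fit_proportional_odds()] result.
#' @param qnet Numeric vector.
#' @return List with `category` (integer vector) and `prob` (n x K matrix,
#'   rows sum to 1).
#' @export
predict_category <- function(model, qnet) {
  eta <- model$beta * qnet
  cum <- cbind(0, stats::plogis(outer(-eta, model$zeta, `+`)), 1)
  prob <- cum[, -1, drop = FALSE] - cum[, -ncol(cum), drop = FALSE]
  colnames(prob) <- paste0("P", seq_len(model$K) - 1)
  assign <- apply(prob, 1, function(p) which(p >= max(p) - 1e-12)[1] - 1L)
  list(category = as.integer(assign), prob = prob)
}

#' Mean absolute prediction error from category fractions
#'
#' `sum_x P(x) * |x - c|`: the mean absolute difference between assigned and
#' actual category over all samples of a drug.
#'
#' @param P Vector of category fractions (sums to 1), names/positions are
#'   categories 0..K-1.
#' @param category True category.
#' @return Scalar in \[0, K-1\].
#' @export
prediction_error <- function(P, category) {
  if (abs(sum(P) - 1) > 1e-6) stop("category fractions must sum to 1")
  x <- seq_along(P) - 1
  sum(P * abs(x - category))
}

#' Leave-one-drug-out cross-validation of TdP risk stratification
#'
#' For each drug: train a proportional-odds classifier on all qNet samples of
#' the remaining drugs, assign each left-out sample to its highest-probability
#' category, report the per-category assignment fractions P(x) and the
#' prediction error, then summarize mean and SD of errors across drugs.
#'
#' @param qnet_by_drug Named list: per drug, the numeric vector of surviving
#'   qNet samples at one concentration multiple.
#' @param labels Named integer vector (or data.frame like [risk_labels()])
#'   of true categories.
#' @return A `loocv_result`: data.frame `per_drug` (drug, category, P0..,
#'   error) plus `mean_error`, `sd_error`, and `failed` (fold names whose
#'   training set degenerated).
#' @export
loocv <- function(qnet_by_drug, labels) {
  if (is.data.frame(labels))
    labels <- stats::setNames(labels$category, labels$drug)
  drugs <- names(qnet_by_drug)
  stopifnot(all(drugs %in% names(labels)))
  K <- max(labels[drugs]) + 1
  rows <- list()
  failed <- character()
  for (d in drugs) {
    train_q <- unlist(qnet_by_drug[setdiff(drugs, d)], use.names = FALSE)
    train_y <- unlist(lapply(setdiff(drugs, d), function(dd)
      rep(labels[[dd]], length(qnet_by_drug[[dd]]))), use.names = FALSE)
    model <- tryCatch(
      suppressWarnings(fit_proportional_odds(train_q, train_y)),
      error = function(e) NULL)
    if (is.null(model)) {
      failed <- c(failed, d)
      next
    }
    pred <- predict_category(model, qnet_by_drug[[d]])
    P <- vapply(seq_len(K) - 1, function(x) mean(pred$category == x),
                numeric(1))
    err <- prediction_error(P, labels[[d]])
    row <- data.frame(drug = d, category = labels[[d]], t(P), error = err)
    names(row)[3:(2 + K)] <- paste0("P", seq_len(K) - 1)
    rows[[d]] <- row
  }
  per_drug <- do.call(rbind, rows)
  rownames(per_drug) <- NULL
  structure(list(per_drug = per_drug,
                 mean_error = mean(per_drug$error),
                 sd_error = stats::sd(per_drug$error),
                 failed = failed),
            class = "loocv_result")
}

#' Remove one current's drug effects from drug-effect samples
#'
#' Returns samples with the named current's block forced to zero: the Hill
#' component dropped for a non-hERG current, or the binding multiplier zeroed
#' for `IKr`.
#'
#' @param samples List of [drug_effect_sample()]s.
#' @param current One of `IKr, ICaL, INaL, INa, Ito, IKs, IK1`.
#' @return Modified sample list.
#' @export
knockout_current <- function(samples, current) {
  valid <- c("IKr", "ICaL", "INaL", "INa", "Ito", "IKs", "IK1")
  if (!current %in% valid)
    stop("unknown current: ", current)
  lapply(samples, function(s) {
    if (current == "IKr") {
      s$binding <- drug_binding_params(Kmax = 0, EC50n = s$binding$EC50n,
                                       n = s$binding$n, Ku = s$binding$Ku,
                                       Vhalftrap = s$binding$Vhalftrap,
                                       Kt = s$binding$Kt)
    } else {
      s$hill[[current]] <- NULL
    }
    s
  })
}

#' Current-knockout LOOCV sensitivity analysis
#'
#' Re-propagates every drug's samples with the named current's drug effects
#' removed and repeats LOOCV at each multiple, quantifying how much risk
#' stratification depends on that current.
#'
#' @param samples_by_drug Named list: per drug, its list of
#'   [drug_effect_sample()]s.
#' @param labels True categories (as in [loocv()]).
#' @param current Current to knock out, or `NULL` for the baseline.
#' @param multiples Concentration multiples (default 1:4).
#' @param ... Passed to [propagate_uncertainty()] / [run_drug_simulation()].
#' @return List with `mean_error` (named by multiple), `loocv` (per
#'   multiple), `current`.
#' @export
current_knockout_loocv <- function(samples_by_drug, labels, current = NULL,
                                   multiples = 1:4, ...) {
  if (!is.null(current))
    samples_by_drug <- lapply(samples_by_drug, knockout_current, current)
  dists <- lapply(samples_by_drug, propagate_uncertainty,
                  multiples = multiples, ...)
  res <- lapply(seq_along(multiples), function(mi) {
    qn <- lapply(dists, function(dd) dd$per_multiple[[mi]]$qnet)
    loocv(qn, labels)
  })
  names(res) <- as.character(multiples)
  list(mean_error = vapply(res, `[[`, numeric(1), "mean_error"),
       loocv = res, current = current)
}
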