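# CMA-ES fitting of drug-hERG binding kinetics to mean fractional-current
# responses, and non-parametric bootstrap over cells for the joint parameter
# sampling distribution.
#
# The five free parameters are fitted in transformed space -- log10 for Kmax,
# EC50^n and Ku (they are reported that way and span orders of magnitude),
# linear for n and Vhalftrap -- with Kt held fixed.

.binding_par_names <- c("log10_Kmax", "log10_EC50n", "n", "log10_Ku",
                        "Vhalftrap")

.binding_from_theta <- function(theta, Kt = 3.5e-5) {
  binding_from_log10(theta[1], theta[2], theta[3], theta[4], theta[5], Kt = Kt)
}

.theta_from_binding <- function(bp) {
  c(log10(bp$Kmax), log10(bp$EC50n), bp$n, log10(bp$Ku), bp$Vhalftrap)
}

#' Default CMA-ES box bounds for the binding parameters
#'
#' @param config Model configuration (the bounds live in the parameter file).
#' @return List with `lower` and `upper` named vectors in the fitting
#'   transform.
#' @export
binding_bounds <- function(config = .default_config()) {
  b <- config$binding_bounds
  lower <- c(b$log10_Kmax[1], b$log10_EC50n[1], b$n[1], b$log10_Ku[1],
             b$Vhalftrap[1])
  upper <- c(b$log10_Kmax[2], b$log10_EC50n[2], b$n[2], b$log10_Ku[2],
             b$Vhalftrap[2])
  names(lower) <- names(upper) <- .binding_par_names
  list(lower = lower, upper = upper)
}

#' Construct a Milnes trace dataset
#'
#' @param traces List of grid x sweeps fractional-current matrices, one per
#'   cell.
#' @param conc Concentration (nM) per cell; a cell appears at exactly one
#'   concentration.
#' @param time_ms Measurement grid shared by all cells.
#' @param cell_id Optional cell identifiers.
#' @param drug Optional drug name.
#' @return A `trace_dataset`.
#' @export
trace_dataset <- function(traces, conc, time_ms, cell_id = NULL,
                          drug = "synthetic") {
  stopifnot(length(traces) == length(conc), length(conc) >= 1)
  if (is.null(cell_id)) cell_id <- paste0("cell", seq_along(traces))
  if (anyDuplicated(cell_id)) stop("duplicate cell identifiers")
  dims <- vapply(traces, dim, integer(2))
  if (any(dims[1, ] != length(time_ms)) || length(unique(dims[2, ])) != 1)
    stop("all cells must share the measurement grid and sweep count")
  structure(list(drug = drug, time_ms = time_ms,
                 sweeps = unique(dims[2, ]),
                 conc = conc, cell_id = cell_id, traces = traces),
            class = "trace_dataset")
}

#' Mean fractional-current response by concentration
#'
#' Pointwise arithmetic mean of the per-cell fractional current traces within
#' each concentration; the tuple of per-concentration means is the fitting
#' target.
#'
#' @param ds A [trace_dataset()].
#' @return A `mean_response`: list with `time_ms`, `sweeps`, `conc` (sorted
#'   unique concentrations) and `mean` (list of grid x sweeps matrices).
#' @export
mean_response <- function(ds) {
  stopifnot(inherits(ds, "trace_dataset"), length(ds$traces) >= 1)
  concs <- sort(unique(ds$conc))
  means <- lapply(concs, function(cc) {
    idx <- which(ds$conc == cc)
    Reduce(`+`, ds$traces[idx]) / length(idx)
  })
  structure(list(time_ms = ds$time_ms, sweeps = ds$sweeps, conc = concs,
                 mean = means, drug = ds$drug),
            class = "mean_response")
}

#' Sum-of-squares loss of binding parameters against a mean response
#'
#' Sum over concentrations, sweeps and time points of squared differences
#' between the Milnes-protocol model prediction and the mean observed
#' fractional current.  Simulation failures yield `Inf` (safe for CMA-ES).
#'
#' @param bp [drug_binding_params()] (or a transformed parameter vector).
#' @param ybar A [mean_response()].
#' @param protocol [milnes_protocol()]; its grid must match the data grid.
#' @param config Model configuration.
#' @param control Optional cached drug-free open-probability trajectory.
#' @return Nonnegative scalar.
#' @export
sse_loss <- function(bp, ybar, protocol = NULL, config = .default_config(),
                     control = NULL) {
  if (is.numeric(bp)) bp <- .binding_from_theta(bp)
  if (is.null(protocol)) protocol <- .protocol_for_response(ybar, config)
  if (is.null(control)) control <- .milnes_open_prob(bp, protocol, 0, config)
  if (!isTRUE(all.equal(control$time_ms, ybar$time_ms)))
    stop("protocol measurement grid does not match the data grid")
  tot <- 0
  for (k in seq_along(ybar$conc)) {
    pred <- tryCatch(
      simulate_milnes(bp, protocol, ybar$conc[k], config, control = control),
      error = function(e) NULL)
    if (is.null(pred)) return(Inf)
    tot <- tot + sum((pred$frac - ybar$mean[[k]])^2)
  }
  tot
}

# protocol whose measurement grid matches a dataset/response grid
.protocol_for_response <- function(y, config = .default_config()) {
  grid_ms <- unique(round(diff(y$time_ms), 10))
  if (length(grid_ms) != 1) stop("data grid is not uniform")
  prot <- milnes_protocol(config, sweeps = y$sweeps, grid_ms = grid_ms)
  meas <- which(prot$segments$measure)
  prot$segments$duration_ms[meas] <- max(y$time_ms)
  prot
}

#' Fit drug-hERG binding parameters with CMA-ES
#'
#' @param ybar A [mean_response()].
#' @param bounds Box bounds from [binding_bounds()] (or the same structure).
#' @param seed Integer seed; the fit is deterministic given it.
#' @param restarts Number of additional CMA-ES restarts from perturbed
#'   starts; the best run wins.
#' @param maxit Generations per run.
#' @param start Optional start vector in the fitting transform (warm start);
#'   default is the box midpoint.
#' @param sigma Initial step size in normalized box coordinates (the search
#'   runs in \[0,1\]^5); default 0.25.
#' @param protocol,config As in [sse_loss()].
#' @return List with `binding` ([drug_binding_params()]), `theta` (named
#'   transformed parameters), `loss`, and `evals`.
#' @export
fit_cmaes <- function(ybar, bounds = binding_bounds(), seed = 1,
                      restarts = 2, maxit = 150, start = NULL, sigma = NULL,
                      protocol = NULL, config = .default_config()) {
  if (is.null(protocol)) protocol <- .protocol_for_response(ybar, config)
  control <- .milnes_open_prob(
    drug_binding_params(0, 1, 1, 1e-5, -100), protocol, 0, config)
  lo <- bounds$lower; up <- bounds$upper
  width <- up - lo
  # optimize in normalized [0,1]^5 coordinates so all parameters share scale
  obj <- function(z) sse_loss(lo + z * width, ybar, protocol, config, control)
  if (is.null(start)) start <- (lo + up) / 2
  z_start <- (start - lo) / width
  z_sigma <- if (is.null(sigma)) 0.25 else sigma
  best <- NULL
  for (r in 0:restarts) {
    s0 <- if (r == 0) z_start else {
      set.seed(.derive_seed(seed, 1000 + r))
      stats::runif(length(lo))
    }
    res <- cma_es(obj, s0, rep(0, length(lo)), rep(1, length(lo)),
                  sigma = z_sigma, maxit = maxit,
                  seed = .derive_seed(seed, r))
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best) || !is.finite(best$value))
    stop("all CMA-ES restarts failed; best loss ",
         if (is.null(best)) NA else best$value)
  theta <- stats::setNames(lo + best$par * width, .binding_par_names)
  list(binding = .binding_from_theta(theta), theta = theta,
       loss = best$value, evals = best$counts)
}

#' Resample a trace dataset for the bootstrap
#'
#' Cells are drawn with replacement independently within each concentration,
#' preserving the per-concentration sample sizes exactly.
#'
#' @param ds A [trace_dataset()].
#' @param seed Integer seed.
#' @return A new `trace_dataset` of identical shape.
#' @export
bootstrap_resample <- function(ds, seed) {
  set.seed(seed)
  idx <- unlist(lapply(sort(unique(ds$conc)), function(cc) {
    at <- which(ds$conc == cc)
    at[sample.int(length(at), length(at), replace = TRUE)]
  }))
  trace_dataset(ds$traces[idx], ds$conc[idx], ds$time_ms,
                cell_id = paste0("resample", seq_along(idx)), drug = ds$drug)
}

#' Bootstrap sampling distribution of the binding parameters
#'
#' For each replicate: resample cells within concentration, average, refit
#' with CMA-ES (warm-started at the full-data optimum).  Replicate seeds are
#' derived from the master seed with a counter scheme, so replicates are
#' reproducible independently of each other.
#'
#' @param ds A [trace_dataset()].
#' @param B Number of bootstrap replicates.
#' @param seed Master seed.
#' @param maxit CMA-ES generations per replicate refit.  Along the
#'   near-linear identifiability ridge the objective is flat, so the spread
#'   of replicate fits along the ridge depends on how far the refits explore;
#'   small caps understate it.
#' @param sigma Initial step size (normalized coordinates) of the
#'   warm-started replicate refits.
#' @param restarts Restarts per replicate (0 is the warm-started default).
#' @param bounds,config As in [fit_cmaes()].
#' @param full_fit Optional precomputed full-data fit (from [fit_cmaes()]).
#' @return A `bootstrap_distribution`: list with `theta` (B x 5 matrix of
#'   transformed parameters), `loss` (per replicate), `full` (the full-data
#'   fit), `failed` (count), `seed`.
#' @export
bootstrap_fit <- function(ds, B = 2000, seed = 1, maxit = 80,
                          sigma = 0.25, restarts = 0,
                          bounds = binding_bounds(),
                          config = .default_config(), full_fit = NULL) {
  stopifnot(B >= 1)
  ybar <- mean_response(ds)
  protocol <- .protocol_for_response(ybar, config)
  if (is.null(full_fit))
    full_fit <- fit_cmaes(ybar, bounds, seed = .derive_seed(seed, 0),
                          protocol = protocol, config = config)
  width <- bounds$upper - bounds$lower
  theta <- matrix(NA_real_, B, length(.binding_par_names),
                  dimnames = list(NULL, .binding_par_names))
  loss <- rep(NA_real_, B)
  failed <- 0L
  for (b in seq_len(B)) {
    res <- tryCatch({
      dsb <- bootstrap_resample(ds, .derive_seed(seed, b))
      yb <- mean_response(dsb)
      fit_cmaes(yb, bounds, seed = .derive_seed(seed, 100000 + b),
                restarts = restarts, maxit = maxit,
                start = full_fit$theta, sigma = sigma,
                protocol = protocol, config = config)
    }, error = function(e) NULL)
    if (is.null(res) || !is.finite(res$loss)) {
      failed <- failed + 1L
    } else {
      theta[b, ] <- res$theta
      loss[b] <- res$loss
    }
  }
  if (failed > 0)
    message("bootstrap_fit: ", failed, " of ", B,
            " replicate fits failed and were dropped")
  ok <- !is.na(loss)
  structure(list(theta = theta[ok, , drop = FALSE], loss = loss[ok],
                 full = full_fit, failed = failed, B = B, seed = seed),
            class = "bootstrap_distribution")
}

#' Summary table of a bootstrap distribution (optimal value + 95% interval)
#'
#' @param bd A [bootstrap_fit()] result.
#' @param level Interval level.
#' @return data.frame with parameter, optimal, lo, hi; includes the derived
#'   ratio `log10_Kmax - log10_EC50n`, the single identifiable combination in
#'   the near-linear binding regime.
#' @export
binding_summary <- function(bd, level = 0.95) {
  th <- cbind(bd$theta,
              log10_ratio = bd$theta[, "log10_Kmax"] - bd$theta[, "log10_EC50n"])
  opt <- c(bd$full$theta,
           log10_ratio = unname(bd$full$theta["log10_Kmax"] -
                                bd$full$theta["log10_EC50n"]))
  rows <- lapply(colnames(th), function(p) {
    ci <- credible_interval(th[, p], level)
    data.frame(parameter = p, optimal = unname(opt[p]),
               lo = unname(ci[1]), hi = unname(ci[2]))
  })
  do.call(rbind, rows)
}
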