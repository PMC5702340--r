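# Dynamic hERG (IKr) Markov model: drug binding and trapping, the modified
# Milnes voltage-clamp protocol, and fractional-current prediction.
#
# Within a constant-voltage clamp segment the bound Markov model is a linear
# time-invariant system, so segments are propagated exactly with matrix
# exponentials (eigendecomposition, with scaling-and-squaring fallback)
# rather than an ODE solver.

#' Drug-hERG binding parameters
#'
#' The five fitted kinetics parameters of the dynamic binding model plus the
#' fixed trapping rate Kt.
#'
#' @param Kmax Maximal binding-rate multiplier (dimensionless, > 0).
#' @param EC50n n-th power of the half-maximal binding concentration (nM^n).
#' @param n Binding Hill coefficient.
#' @param Ku Unbinding rate (ms^-1).
#' @param Vhalftrap Trapping half-potential (mV).
#' @param Kt Trapping rate (ms^-1); fixed at 3.5e-5 by default and not fitted.
#' @return A `drug_binding_params` list.
#' @export
drug_binding_params <- function(Kmax, EC50n, n, Ku, Vhalftrap, Kt = 3.5e-5) {
  stopifnot(Kmax >= 0, EC50n > 0, Ku > 0, is.finite(n), is.finite(Vhalftrap))
  structure(list(Kmax = Kmax, EC50n = EC50n, n = n, Ku = Ku,
                 Vhalftrap = Vhalftrap, Kt = Kt),
            class = "drug_binding_params")
}

#' Binding parameters from log10-transformed values
#'
#' Convenience constructor matching the reporting convention for the fitted
#' parameters (log10 for Kmax, EC50^n and Ku; linear n and Vhalftrap).
#'
#' @param log10_Kmax,log10_EC50n,n,log10_Ku,Vhalftrap Transformed values.
#' @param Kt Trapping rate (ms^-1).
#' @return A [drug_binding_params()] object.
#' @export
binding_from_log10 <- function(log10_Kmax, log10_EC50n, n, log10_Ku,
                               Vhalftrap, Kt = 3.5e-5) {
  drug_binding_params(Kmax = 10^log10_Kmax, EC50n = 10^log10_EC50n, n = n,
                      Ku = 10^log10_Ku, Vhalftrap = Vhalftrap, Kt = Kt)
}

#' Published hERG binding parameters for the CiPA training compounds
#'
#' Optimal fitted values (FDA CiPA initiative; Li et al. 2017) shipped as a
#' CSV; used as ground-truth fixtures by the synthetic-data generators.
#'
#' @return data.frame with one row per drug (log10-transformed columns plus
#'   bootstrap 95\% interval bounds).
#' @export
herg_binding_table <- function() {
  utils::read.csv(system.file("extdata", "herg_binding_parameters.csv",
                              package = "qnetuq"))
}

#' Concentration dependence of the drug-hERG on-rate (Emax equation)
#'
#' `Kmax * D^n / (D^n + EC50^n)`: sigmoidal in concentration, near-linear
#' (`(Kmax/EC50^n) * D^n`) when `EC50^n >> D^n`, which is the regime in which
#' only the ratio `Kmax/EC50^n` is identifiable.
#'
#' @param bp [drug_binding_params()].
#' @param D Drug concentration (nM), vectorized.
#' @return Dimensionless binding multiplier; the Markov on-rate is this value
#'   times `Ku`.
#' @export
binding_rate_emax <- function(bp, D) {
  if (any(D < 0)) stop("concentration must be >= 0")
  Dn <- ifelse(D > 0, D^bp$n, 0)
  bp$Kmax * Dn / (Dn + bp$EC50n)
}

#' Steady-state open-bound to closed-bound (trapping) fraction
#'
#' The sigmoid `1 / (1 + exp(-(V - Vhalftrap)/k))` giving the steady-state
#' ratio of open-bound (untrapped) to closed-bound (trapped) drug-channel
#' states; equals 1/2 at `V = Vhalftrap` and increases with V.  High-risk
#' compounds sit near 0 at the -80 mV diastolic potential (strong trapping),
#' low-risk compounds near 1.
#'
#' @param V Membrane potential (mV), vectorized.
#' @param Vhalftrap Trapping half-potential (mV).
#' @param k Sigmoid slope (mV), > 0; default from the model configuration.
#' @export
trapping_open_fraction <- function(V, Vhalftrap,
                                   k = .default_config()$ikr_markov$trapping$slope_mV) {
  if (k <= 0) stop("trapping slope k must be > 0")
  stats::plogis((V - Vhalftrap) / k)
}

# Cache of per-config Markov rate constants (A, B, temperature factor per
# named transition), avoiding repeated list traversal in fitting loops.
.markov_consts <- function(config = .default_config()) {
  key <- paste0("mkc_", config$path)
  mc <- .qnetuq_env[[key]]
  if (is.null(mc)) {
    mk <- config$ikr_markov
    qpow <- (mk$temp_c - 20) / 10
    A <- vapply(.markov_rate_names, function(nm) mk$rates[[nm]]$A, 0)
    B <- vapply(.markov_rate_names, function(nm) mk$rates[[nm]]$B, 0)
    qf <- vapply(.markov_rate_names, function(nm) mk$rates[[nm]]$q^qpow, 0)
    mc <- list(A = A * qf, B = B, slope = mk$trapping$slope_mV)
    .qnetuq_env[[key]] <- mc
  }
  mc
}

# Generator matrix A (dx/dt = A x) of the 9-state bound Markov model at
# constant voltage V and concentration D.  State order: IC1 IC2 C1 C2 O IO
# IObound Obound Cbound (indices 1..9).
.markov_generator <- function(V, D, bp, config = .default_config()) {
  mc <- .markov_consts(config)
  r <- mc$A * exp(mc$B * V)
  kon <- bp$Ku * binding_rate_emax(bp, D)
  ku_io <- bp$Ku * r[["A53"]] / r[["A63"]] # microscopic reversibility
  trap_open <- bp$Kt * stats::plogis((V - bp$Vhalftrap) / mc$slope)
  A <- matrix(0, 9, 9, dimnames = list(.markov_state_names,
                                       .markov_state_names))
  # A[to, from] = rate(from -> to)
  A[4, 3] <- r[["A1"]];  A[3, 4] <- r[["A2"]]   # C1 <-> C2
  A[6, 2] <- r[["A3"]];  A[2, 6] <- r[["A4"]]   # IC2 <-> IO
  A[2, 1] <- r[["A11"]]; A[1, 2] <- r[["A21"]]  # IC1 <-> IC2
  A[5, 4] <- r[["A31"]]; A[4, 5] <- r[["A41"]]  # C2 <-> O
  A[1, 3] <- r[["A51"]]; A[3, 1] <- r[["A61"]]  # C1 <-> IC1
  A[2, 4] <- r[["A52"]]; A[4, 2] <- r[["A62"]]  # C2 <-> IC2
  A[6, 5] <- r[["A53"]]; A[5, 6] <- r[["A63"]]  # O <-> IO
  A[8, 5] <- kon;        A[5, 8] <- bp$Ku       # O <-> Obound
  A[7, 6] <- kon;        A[6, 7] <- ku_io       # IO <-> IObound
  A[8, 9] <- trap_open;  A[9, 8] <- bp$Kt       # Cbound <-> Obound
  A[7, 9] <- trap_open;  A[9, 7] <- bp$Kt       # Cbound <-> IObound
  diag(A) <- -colSums(A)
  A
}

# Prepare an LTI propagator for generator A: eigendecomposition when well
# conditioned, expm-stepping fallback otherwise.
.lti_decomp <- function(A) {
  ev <- tryCatch(eigen(A), error = function(e) NULL)
  if (!is.null(ev) && all(is.finite(ev$values))) {
    Vinv <- tryCatch(solve(ev$vectors), error = function(e) NULL)
    if (!is.null(Vinv)) {
      kappa <- max(Mod(ev$vectors)) * max(Mod(Vinv))
      if (is.finite(kappa) && kappa < 1e10)
        return(list(A = A, ev = ev, Vinv = Vinv))
    }
  }
  list(A = A, ev = NULL, Vinv = NULL)
}

# x(t) for an LTI segment at segment-local times >= 0.
.propagate_lti <- function(dec, x0, times) {
  if (!is.null(dec$ev)) {
    C0 <- dec$Vinv %*% x0
    X <- Re(dec$ev$vectors %*% (exp(outer(dec$ev$values, times)) * c(C0)))
    drift <- max(abs(colSums(X) - sum(x0)))
    if (is.finite(drift) && drift < 1e-8) {
      rownames(X) <- names(x0)
      return(X)
    }
  }
  X <- matrix(0, length(x0), length(times))
  dts <- diff(c(0, times))
  x <- x0
  prev_dt <- NA
  E <- NULL
  for (k in seq_along(times)) {
    if (!isTRUE(all.equal(dts[k], prev_dt))) {
      E <- as.matrix(Matrix::expm(dec$A * dts[k]))
      prev_dt <- dts[k]
    }
    x <- E %*% x
    X[, k] <- x
  }
  rownames(X) <- names(x0)
  X
}

#' Milnes voltage-clamp protocol
#'
#' @param config Model configuration (segments are data in the parameter
#'   file); or supply `segments` directly.
#' @param segments data.frame with columns `voltage_mV`, `duration_ms`,
#'   `measure` (exactly one segment must be the measurement step).
#' @param sweeps Number of sweeps.
#' @param grid_ms Uniform measurement grid spacing (ms).
#' @return A `voltage_protocol` list.
#' @export
milnes_protocol <- function(config = .default_config(), segments = NULL,
                            sweeps = NULL, grid_ms = NULL) {
  mp <- config$milnes_protocol
  if (is.null(segments))
    segments <- do.call(rbind, lapply(mp$segments, as.data.frame))
  if (is.null(sweeps)) sweeps <- mp$sweeps
  if (is.null(grid_ms)) grid_ms <- mp$grid_ms
  stopifnot(all(segments$duration_ms > 0), sum(segments$measure) == 1,
            sweeps >= 1, grid_ms > 0)
  structure(list(segments = segments, sweeps = sweeps, grid_ms = grid_ms),
            class = "voltage_protocol")
}

# Drug-free steady-state occupancy at a holding potential (bp-independent:
# with no drug on-rate the bound states empty out), cached per voltage.
.markov_steady_state <- function(V, config = .default_config()) {
  key <- paste0("mss_", config$path, "_", V)
  cached <- .qnetuq_env[[key]]
  if (!is.null(cached)) return(cached)
  bp0 <- drug_binding_params(Kmax = 0, EC50n = 1, n = 1, Ku = 1e-5,
                             Vhalftrap = -100)
  A <- .markov_generator(V, 0, bp0, config)
  M <- rbind(A, rep(1, 9))
  x <- qr.solve(M, c(rep(0, 9), 1))
  x[x < 0] <- 0
  x <- stats::setNames(x / sum(x), .markov_state_names)
  .qnetuq_env[[key]] <- x
  x
}

# Open-probability matrix (measurement grid x sweeps) of the bound Markov
# model over the full protocol at concentration D, starting from the drug-free
# steady state at the first segment's holding potential.
#
# Segments are piecewise-constant in voltage, so each is an LTI system:
# sweep-start states are chained with precomputed real end-of-segment
# propagators, and the dense measurement output for all sweeps is evaluated
# in one (grid x modes) %*% (modes x sweeps) multiply in eigenspace.
.milnes_open_prob <- function(bp, protocol, D, config = .default_config()) {
  seg <- protocol$segments
  meas <- which(seg$measure)
  grid <- seq(protocol$grid_ms, seg$duration_ms[meas],
              by = protocol$grid_ms)
  volts <- unique(seg$voltage_mV)
  dec <- lapply(volts, function(v)
    .lti_decomp(.markov_generator(v, D, bp, config)))
  names(dec) <- as.character(volts)
  fast <- !vapply(dec, function(d) is.null(d$ev), logical(1))
  x <- .markov_steady_state(seg$voltage_mV[1], config)
  S <- protocol$sweeps
  open <- matrix(NA_real_, length(grid), S)

  if (all(fast)) {
    # real end-of-segment propagators
    Eend <- lapply(seq_len(nrow(seg)), function(g) {
      d <- dec[[as.character(seg$voltage_mV[g])]]
      Re(d$ev$vectors %*% (exp(d$ev$values * seg$duration_ms[g]) * d$Vinv))
    })
    dm <- dec[[as.character(seg$voltage_mV[meas])]]
    Etl <- exp(outer(grid, dm$ev$values))      # grid x modes
    o_row <- which(.markov_state_names == "O")
    Vo <- dm$ev$vectors[o_row, ]               # mode weights for state O
    X0s <- matrix(NA_real_, 9, S)
    for (s in seq_len(S)) {
      for (g in seq_len(nrow(seg))) {
        if (g == meas) X0s[, s] <- x
        x <- drop(Eend[[g]] %*% x)
      }
      if (abs(sum(x) - 1) > 1e-4)
        stop("IKr occupancy drift exceeded 1e-4 during clamp simulation")
    }
    C0s <- dm$Vinv %*% X0s                     # modes x sweeps
    open[] <- Re(Etl %*% (Vo * C0s))
  } else {
    for (s in seq_len(S)) {
      for (g in seq_len(nrow(seg))) {
        key <- as.character(seg$voltage_mV[g])
        tt <- if (g == meas) grid else seg$duration_ms[g]
        if (tt[length(tt)] < seg$duration_ms[g])
          tt <- c(tt, seg$duration_ms[g])
        X <- .propagate_lti(dec[[key]], x, tt)
        if (g == meas) open[, s] <- X["O", seq_along(grid)]
        x <- X[, ncol(X)]
        if (abs(sum(x) - 1) > 1e-4)
          stop("IKr occupancy drift exceeded 1e-4 during clamp simulation")
      }
    }
  }
  list(time_ms = grid, open = open)
}

#' Simulate the Milnes protocol and return fractional current
#'
#' Integrates the Markov model over all sweeps twice from identical drug-free
#' initial occupancies -- once with drug at concentration `D`, once without --
#' and returns the open-probability ratio (drug/control) on the measurement
#' segment of each sweep, the model's prediction of the fractional hERG
#' current.
#'
#' @param bp [drug_binding_params()].
#' @param protocol [milnes_protocol()].
#' @param D Concentration (nM); `D = 0` returns all-ones.
#' @param config Model configuration.
#' @param control Optional precomputed drug-free open-probability matrix (the
#'   control trajectory does not depend on the binding parameters); used to
#'   avoid recomputation in fitting loops.
#' @return A `fractional_current_trace`: list with `time_ms` (grid within the
#'   measurement segment, shared by all sweeps), `frac` (grid x sweeps
#'   matrix), `conc` and `sweeps`.
#' @export
simulate_milnes <- function(bp, protocol = milnes_protocol(), D,
                            config = .default_config(), control = NULL) {
  if (D < 0) stop("concentration must be >= 0")
  if (is.null(control)) control <- .milnes_open_prob(bp, protocol, 0, config)
  if (D == 0) {
    frac <- control$open
    frac[] <- 1
  } else {
    drugged <- .milnes_open_prob(bp, protocol, D, config)
    frac <- drugged$open / pmax(control$open, 1e-12)
  }
  structure(list(time_ms = control$time_ms, frac = frac, conc = D,
                 sweeps = protocol$sweeps),
            class = "fractional_current_trace")
}
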