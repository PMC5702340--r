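# CiPAORdv1.0 cell model interface: parameter handling, single-derivative
# evaluation, pacing, steady state, and qNet bookkeeping.  The ODE right-hand
# side lives in src/cipaord.c and is integrated with deSolve::lsoda.

.qnetuq_env <- new.env(parent = emptyenv())

#' Load the CiPAORdv1.0 model configuration
#'
#' Reads the versioned structured parameter file shipped with the package
#' (base O'Hara-Rudy endocardial constants, the Li et al. IKr Markov gating
#' constants, Dutta et al. conductance scalings, pacing and solver defaults,
#' the modified Milnes protocol and fitting bounds).
#'
#' @param path Path to a YAML parameter file; default is the packaged
#'   `cipaordv1.yaml`.
#' @return A named list with the file's sections plus `$path`.
#' @export
cipaord_config <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "cipaordv1.yaml", package = "qnetuq")
  }
  cfg <- yaml::read_yaml(path)
  cfg$path <- path
  cfg
}

.default_config <- function() {
  if (is.null(.qnetuq_env$config)) .qnetuq_env$config <- cipaord_config()
  .qnetuq_env$config
}

.state_names <- c(
  "V", "nai", "nass", "ki", "kss", "cai", "cass", "cansr", "cajsr",
  "m", "hf", "hs", "j", "hsp", "jp", "mL", "hL", "hLp",
  "a", "iF", "iS", "ap", "iFp", "iSp",
  "d", "ff", "fs", "fcaf", "fcas", "jca", "nca", "ffp", "fcafp",
  "xs1", "xs2", "xk1", "Jrelnp", "Jrelp", "CaMKt",
  "IC1", "IC2", "C1", "C2", "O", "IO", "IObound", "Obound", "Cbound",
  "qNet"
)

.markov_state_names <- c("IC1", "IC2", "C1", "C2", "O", "IO",
                         "IObound", "Obound", "Cbound")

.current_names <- c("IKr", "ICaL", "INaL", "Ito", "IKs", "IK1")

.markov_rate_names <- c("A1", "A2", "A3", "A4", "A11", "A21", "A31", "A41",
                        "A51", "A61", "A52", "A62", "A53", "A63")

#' Default conductance scaling (Dutta et al. optimized factors)
#'
#' @param identity If `TRUE`, return identity scaling (all ones), which
#'   recovers the unscaled IKr-dynamic ORd model.
#' @param config Model configuration list.
#' @return Named numeric vector over the seven scalable currents.
#' @export
conductance_scaling <- function(identity = FALSE, config = .default_config()) {
  s <- unlist(config$scaling)[c("INa", "INaL", "Ito", "ICaL", "IKr", "IKs", "IK1")]
  if (identity) s[] <- 1
  if (any(!is.finite(s)) || any(s <= 0)) stop("scaling factors must be > 0")
  s
}

#' Pacing protocol constructor
#'
#' @param cl Cycle length (ms).
#' @param amp Stimulus amplitude (uA/uF); applied as a depolarizing current.
#' @param dur Stimulus duration (ms).
#' @param beats Number of paced beats.
#' @return A `pacing_protocol` list.
#' @export
pacing_protocol <- function(cl = 2000, amp = -80, dur = 0.5, beats = 1000) {
  stopifnot(cl > dur, dur > 0, beats >= 1)
  structure(list(cl = cl, amp = amp, dur = dur, beats = beats),
            class = "pacing_protocol")
}

#' Zero drug effect (no channel block, zero concentration)
#'
#' @param binding Optional [drug_binding_params()]; any drug's parameters give
#'   identical model behaviour at zero concentration.
#' @return A `drug_effect` list with all block fractions 0 and `conc = 0`.
#' @export
no_drug <- function(binding = NULL) {
  drug_effect(block = c(INa = 0, INaL = 0, Ito = 0, ICaL = 0, IKs = 0, IK1 = 0),
              binding = binding, conc = 0)
}

#' Drug effect on the cell model
#'
#' Combines static Hill pore block of the six non-hERG currents with the
#' dynamic hERG binding parameters and a drug concentration.  IKr is never
#' Hill-scaled; its block emerges from the Markov binding states.
#'
#' @param block Named block fractions in \[0,1\] for any of
#'   `INa, INaL, Ito, ICaL, IKs, IK1` (missing entries are 0).
#' @param binding A [drug_binding_params()] object or `NULL` (no binding).
#' @param conc Drug concentration (nM).
#' @return A `drug_effect` list.
#' @export
drug_effect <- function(block = NULL, binding = NULL, conc = 0) {
  b <- c(INa = 0, INaL = 0, Ito = 0, ICaL = 0, IKs = 0, IK1 = 0)
  if (!is.null(block)) {
    bad <- setdiff(names(block), names(b))
    if (length(bad)) stop("unknown current in block fractions: ",
                          paste(bad, collapse = ", "))
    b[names(block)] <- block
  }
  if (any(b < 0 | b > 1)) stop("block fractions must be in [0, 1]")
  if (conc < 0) stop("drug concentration must be >= 0")
  structure(list(block = b, binding = binding, conc = conc),
            class = "drug_effect")
}

# Pack the deSolve parameter vector expected by src/cipaord.c (84 values;
# order must match the #define block there).
.pack_parms <- function(scaling, effect, istim = 0, config = .default_config()) {
  ph <- config$physical
  g <- config$conductances
  mk <- config$ikr_markov
  bp <- effect$binding
  if (is.null(bp)) bp <- drug_binding_params(Kmax = 0, EC50n = 1, n = 1,
                                             Ku = 1e-5, Vhalftrap = -100)
  rates <- unlist(lapply(.markov_rate_names, function(nm) {
    r <- mk$rates[[nm]]
    c(r$A, r$B, r$q)
  }))
  p <- c(ph$nao, ph$cao, ph$ko, ph$Rgas, ph$Temp, ph$Frdy,
         g$GNa, g$GNaL, g$Gto, g$PCa, g$GKr, g$GKs, g$GK1,
         g$Gncx, g$Pnak, g$GKb, g$PNab, g$PCab, g$GpCa,
         scaling[["INa"]], scaling[["INaL"]], scaling[["Ito"]],
         scaling[["ICaL"]], scaling[["IKr"]], scaling[["IKs"]], scaling[["IK1"]],
         effect$block[["INa"]], effect$block[["INaL"]], effect$block[["Ito"]],
         effect$block[["ICaL"]], effect$block[["IKs"]], effect$block[["IK1"]],
         istim,
         rates,
         mk$temp_c, mk$trapping$Kt, mk$trapping$slope_mV,
         bp$Kmax, bp$EC50n, bp$n, bp$Ku, bp$Vhalftrap,
         effect$conc)
  stopifnot(length(p) == 84)
  p
}

#' Initial model state
#'
#' The published O'Hara-Rudy endocardial initial conditions from the parameter
#' file, used as the starting point for pacing-to-convergence.
#'
#' @param config Model configuration list.
#' @return Named state vector (49 components, including the qNet accumulator).
#' @export
initial_state <- function(config = .default_config()) {
  y <- unlist(config$initial_state)[.state_names]
  if (any(is.na(y))) stop("parameter file is missing initial state components")
  y
}

.check_state <- function(state) {
  if (any(!is.finite(state))) {
    bad <- .state_names[!is.finite(state)]
    stop("non-finite state component(s): ", paste(bad, collapse = ", "))
  }
  occ <- state[.markov_state_names]
  if (any(occ < -1e-6) || abs(sum(occ) - 1) > 1e-4)
    stop("IKr Markov occupancies violate conservation (sum = ",
         format(sum(occ)), ")")
  conc <- state[c("nai", "nass", "ki", "kss", "cai", "cass", "cansr", "cajsr")]
  if (any(conc <= 0)) stop("non-positive ionic concentration in state")
  invisible(TRUE)
}

#' Evaluate the model time derivative at a state
#'
#' Single right-hand-side evaluation of the CiPAORdv1.0 ODE system, including
#' the qNet accumulator derivative (instantaneous sum of the six major
#' currents, in uC/uF per ms).
#'
#' @param state Named 49-component state vector (see [initial_state()]).
#' @param t Time (ms); the autonomous model ignores it except for bookkeeping.
#' @param scaling Conductance scaling vector from [conductance_scaling()].
#' @param effect Drug effect from [drug_effect()] / [no_drug()].
#' @param istim Applied stimulus current (uA/uF).
#' @param config Model configuration.
#' @return List with `dstate` (named derivative) and `currents` (named vector
#'   `IKr, ICaL, INaL, Ito, IKs, IK1, Inet` in uA/uF).
#' @export
derivatives <- function(state, t = 0, scaling = conductance_scaling(),
                        effect = no_drug(), istim = 0,
                        config = .default_config()) {
  state <- state[.state_names]
  .check_state(state)
  p <- .pack_parms(scaling, effect, istim, config)
  .C("qnetuq_setparms", as.double(p), as.integer(length(p)),
     PACKAGE = "qnetuq")
  out <- .C("qnetuq_derivs_eval", as.double(t), as.double(state),
            ydot = double(49), yout = double(7), PACKAGE = "qnetuq")
  dstate <- out$ydot
  names(dstate) <- .state_names
  currents <- out$yout
  names(currents) <- c(.current_names, "Inet")
  list(dstate = dstate, currents = currents)
}

# Integrate one beat: stimulus on for protocol$dur, then off until cl.
# Returns the lsoda dense output on `times` (ms, beat-local) and final state.
.integrate_beat <- function(y, protocol, parms_on, parms_off, times,
                            rtol, atol, beat_index = NA) {
  dur <- protocol$dur
  t_on <- sort(unique(c(0, times[times <= dur], dur)))
  t_off <- sort(unique(c(dur, times[times >= dur], protocol$cl)))
  run <- function(tt, pp, y0) {
    out <- try(deSolve::lsoda(
      y = y0, times = tt, func = "qnetuq_derivs", parms = pp,
      dllname = "qnetuq", initfunc = "qnetuq_initmod", nout = 7,
      outnames = c(.current_names, "Inet"),
      rtol = rtol, atol = atol, maxsteps = 50000), silent = TRUE)
    if (inherits(out, "try-error") || any(!is.finite(out[nrow(out), 2:50])))
      stop("solver failure at beat ", beat_index, "; last state: V = ",
           format(y0[["V"]]), call. = FALSE)
    out
  }
  out1 <- run(t_on, parms_on, y)
  y_mid <- out1[nrow(out1), 1 + seq_len(49)]
  names(y_mid) <- .state_names
  out2 <- run(t_off, parms_off, y_mid)
  y_end <- out2[nrow(out2), 1 + seq_len(49)]
  names(y_end) <- .state_names
  dense <- rbind(out1[out1[, 1] %in% times, , drop = FALSE],
                 out2[out2[, 1] %in% times & out2[, 1] > dur, , drop = FALSE])
  list(dense = dense, state = y_end)
}

#' Pace the cell model
#'
#' Integrates the model continuously (no state resets) for
#' `protocol$beats` beats, applying the stimulus for `protocol$dur` ms at the
#' start of each cycle.  Dense output on a uniform grid is retained only for
#' the final `keep_beats` analysis window to bound memory.
#'
#' @param init Initial state (e.g. [initial_state()] or a cached steady
#'   state).
#' @param protocol A [pacing_protocol()].
#' @param scaling Conductance scaling.
#' @param effect Drug effect.
#' @param keep_beats Number of trailing beats to retain dense output for.
#' @param dt Output grid spacing (ms) within retained beats.
#' @param rtol,atol Solver tolerances (default 1e-6/1e-6; pass
#'   `rtol = 1e-3` for relaxed bootstrap-style runs).
#' @param config Model configuration.
#' @return List with `beats` (list of per-beat data.frames: `time_ms`, `Vm_mV`,
#'   the six currents, `Inet`, `qNet`), `state` (final state), and
#'   `qnet_start` (accumulator value at the start of each retained beat).
#' @export
run_pacing <- function(init, protocol = pacing_protocol(),
                       scaling = conductance_scaling(), effect = no_drug(),
                       keep_beats = min(250, protocol$beats), dt = 1,
                       rtol = NULL, atol = NULL, config = .default_config()) {
  if (is.null(rtol)) rtol <- config$solver$rtol
  if (is.null(atol)) atol <- config$solver$atol
  y <- init[.state_names]
  .check_state(y)
  parms_on <- .pack_parms(scaling, effect, protocol$amp, config)
  parms_off <- .pack_parms(scaling, effect, 0, config)
  times <- seq(0, protocol$cl, by = dt)
  keep_from <- protocol$beats - keep_beats + 1
  beats <- vector("list", keep_beats)
  qnet_start <- numeric(keep_beats)
  for (b in seq_len(protocol$beats)) {
    keep <- b >= keep_from
    tt <- if (keep) times else c(0, protocol$cl)
    res <- .integrate_beat(y, protocol, parms_on, parms_off, tt,
                           rtol, atol, beat_index = b)
    if (keep) {
      k <- b - keep_from + 1
      d <- as.data.frame(res$dense)
      qnet_start[k] <- y[["qNet"]]
      beats[[k]] <- data.frame(
        time_ms = d$time,
        Vm_mV = d$V,
        IKr = d$IKr, ICaL = d$ICaL, INaL = d$INaL,
        Ito = d$Ito, IKs = d$IKs, IK1 = d$IK1,
        Inet = d$Inet, qNet = d$qNet)
    }
    y <- res$state
  }
  occ <- y[.markov_state_names]
  if (abs(sum(occ) - 1) > 1e-4)
    stop("IKr occupancy drift exceeded tolerance during pacing")
  list(beats = beats, state = y, qnet_start = qnet_start,
       protocol = protocol)
}

#' Control (no-drug) steady state
#'
#' Paces from the published initial conditions until the maximum relative
#' change of all state components between consecutive cycle starts falls
#' below `tol`, or `max_beats` is reached (then a warning is issued and the
#' best state returned).  The result is cached per (cycle length, scaling,
#' tolerance) in the package environment and optionally in a file.
#'
#' @param protocol A [pacing_protocol()]; only `cl`, `amp`, `dur` are used.
#' @param scaling Conductance scaling.
#' @param tol Convergence tolerance on the max relative state change per beat.
#' @param max_beats Beat cap.
#' @param cache_file Optional path for a text cache of the converged state.
#' @param config Model configuration.
#' @return Named steady state vector with attribute `convergence` (the final
#'   per-beat relative change) and `beats_run`.
#' @export
control_steady_state <- function(protocol = pacing_protocol(),
                                 scaling = conductance_scaling(),
                                 tol = 1e-6, max_beats = 2000,
                                 cache_file = NULL,
                                 config = .default_config()) {
  key <- paste0("ss_", protocol$cl, "_", protocol$dur, "_", protocol$amp, "_",
                paste(signif(scaling, 8), collapse = "_"), "_", tol)
  if (!is.null(.qnetuq_env[[key]])) return(.qnetuq_env[[key]])
  if (!is.null(cache_file) && file.exists(cache_file)) {
    tab <- utils::read.csv(cache_file)
    y <- stats::setNames(tab$value, tab$state)[.state_names]
    .qnetuq_env[[key]] <- y
    return(y)
  }
  effect <- no_drug()
  parms_on <- .pack_parms(scaling, effect, protocol$amp, config)
  parms_off <- .pack_parms(scaling, effect, 0, config)
  y <- initial_state(config)
  rtol <- config$solver$rtol; atol <- config$solver$atol
  delta <- Inf
  b <- 0
  scale_ref <- pmax(abs(y), 1e-7)
  while (b < max_beats) {
    b <- b + 1
    res <- .integrate_beat(y, protocol, parms_on, parms_off,
                           c(0, protocol$cl), rtol, atol, beat_index = b)
    y_new <- res$state
    y_new[["qNet"]] <- 0 # accumulator is not part of the physiological state
    y0 <- y; y0[["qNet"]] <- 0
    delta <- max(abs(y_new - y0) / pmax(abs(y0), 1e-7))
    y <- y_new
    if (delta < tol) break
  }
  if (delta >= tol)
    warning("steady state not converged within ", max_beats,
            " beats (max relative change ", format(delta), ")")
  attr(y, "convergence") <- delta
  attr(y, "beats_run") <- b
  .qnetuq_env[[key]] <- y
  if (!is.null(cache_file)) {
    utils::write.csv(data.frame(state = .state_names, value = as.numeric(y)),
                     cache_file, row.names = FALSE)
  }
  y
}

#' Export dense beat output as delimited text
#'
#' @param beat A per-beat data.frame from [run_pacing()].
#' @param path Output file.
#' @export
write_beat_trace <- function(beat, path) {
  utils::write.csv(beat[, c("time_ms", "Vm_mV", "IKr", "ICaL", "INaL",
                            "Ito", "IKs", "IK1", "qNet")],
                   path, row.names = FALSE)
}
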