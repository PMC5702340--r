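# TdP-risk simulation protocol: beat classification (EAD / depolarization
# failure), qNet computation, per-sample drug simulations, and propagation of
# paired uncertainty samples across the concentration grid.

#' Classify a single beat
#'
#' Applies the depolarization rule (Vm must exceed 0 mV), locates the 30% and
#' 90% repolarization levels relative to the takeoff potential (Vm at
#' stimulus onset), and computes the maximum repolarization-phase slope
#' dV/dt_repol with the three-case window rule: 30-90% repolarization when
#' the beat fully repolarizes; 30% to end of beat when it reaches 30% but not
#' 90%; AP peak to end of beat otherwise.  An EAD is any beat with
#' dV/dt_repol > 0.
#'
#' @param time_ms Uniform time grid for one cycle (ms).
#' @param vm Membrane potential (mV) on that grid.
#' @return A `beat_summary`: list with `depolarized`, `vpeak`, `vtakeoff`,
#'   `t_repol30`, `t_repol90` (ms or NA), `dvdt_repol` (mV/ms, NA when not
#'   depolarized), `ead`.
#' @export
classify_beat <- function(time_ms, vm) {
  stopifnot(length(time_ms) == length(vm), length(vm) >= 3)
  dt <- diff(time_ms)
  if (max(abs(dt - dt[1])) > 1e-6 * dt[1])
    stop("classify_beat requires a uniform time grid")
  dt <- dt[1]
  vtakeoff <- vm[1]
  pk <- which.max(vm)
  vpeak <- vm[pk]
  depolarized <- vpeak > 0
  if (!depolarized) {
    return(structure(list(depolarized = FALSE, vpeak = vpeak,
                          vtakeoff = vtakeoff, t_repol30 = NA_real_,
                          t_repol90 = NA_real_, dvdt_repol = NA_real_,
                          ead = FALSE),
                     class = "beat_summary"))
  }
  lvl <- function(x) vpeak - (x / 100) * (vpeak - vtakeoff)
  after <- pk:length(vm)
  i30 <- after[which(vm[after] <= lvl(30))[1]]
  i90 <- after[which(vm[after] <= lvl(90))[1]]
  from <- if (!is.na(i30)) i30 else pk
  to <- if (!is.na(i30) && !is.na(i90)) i90 else length(vm)
  dvdt_repol <- if (to - from >= 2) {
    v <- vm[from:to]
    max((v[3:length(v)] - v[1:(length(v) - 2)]) / (2 * dt))
  } else if (to > from) {
    (vm[to] - vm[from]) / dt
  } else {
    -Inf
  }
  structure(list(depolarized = TRUE, vpeak = vpeak, vtakeoff = vtakeoff,
                 t_repol30 = if (is.na(i30)) NA_real_ else time_ms[i30],
                 t_repol90 = if (is.na(i90)) NA_real_ else time_ms[i90],
                 dvdt_repol = dvdt_repol, ead = dvdt_repol > 0),
            class = "beat_summary")
}

#' qNet of one beat
#'
#' Net charge carried by the six major currents over the beat, from the
#' integrated accumulator state (difference across the beat).  Cross-check
#' against [qnet_trapz()] for the same beat.
#'
#' @param beat A per-beat data.frame from [run_pacing()] (columns `time_ms`,
#'   `qNet`, ...), covering one full cycle.
#' @param cl Expected cycle length (ms); the window must cover it.
#' @return qNet (uC/uF).
#' @export
compute_qnet <- function(beat, cl = NULL) {
  if (!is.null(cl) &&
      (max(beat$time_ms) - min(beat$time_ms)) < cl - 1e-6)
    stop("beat window shorter than the cycle length")
  beat$qNet[nrow(beat)] - beat$qNet[1]
}

#' Trapezoidal-quadrature qNet (independent cross-check)
#'
#' Integrates the logged sum of the six currents over the dense output by the
#' trapezoid rule; agrees with the accumulator within solver accuracy.
#'
#' @param beat A per-beat data.frame with `time_ms` and `Inet` (uA/uF).
#' @return qNet (uC/uF).
#' @export
qnet_trapz <- function(beat) {
  t <- beat$time_ms
  f <- beat$Inet
  sum(diff(t) * (utils::head(f, -1) + utils::tail(f, -1)) / 2) / 1000
}

#' Select the beat used for qNet
#'
#' The beat with the steepest membrane-potential reactivation (maximum
#' dV/dt_repol) among depolarized beats, whether or not an EAD occurred; ties
#' resolve to the earliest beat.
#'
#' @param summaries List of [classify_beat()] results.
#' @return Index into `summaries`, or `NA` if no beat depolarized.
#' @export
select_qnet_beat <- function(summaries) {
  dv <- vapply(summaries, function(s)
    if (s$depolarized) s$dvdt_repol else -Inf, numeric(1))
  if (all(!is.finite(dv))) return(NA_integer_)
  which.max(dv) # which.max takes the first maximum: earliest beat on ties
}

#' One paired draw from all drug-effect uncertainty distributions
#'
#' @param binding A [drug_binding_params()] draw.
#' @param hill Named list over currents (`ICaL`, `INaL`, `INa`, `Ito`, `IKs`,
#'   `IK1`) of [hill_params()] draws or `NULL` (null effect: 0% block).
#' @param cmax Maximum therapeutic concentration (nM), > 0.
#' @param index Sample index (alignment across source distributions).
#' @param drug Drug name.
#' @return A `drug_effect_sample`.
#' @export
drug_effect_sample <- function(binding, hill = list(), cmax, index = 1L,
                               drug = "synthetic") {
  stopifnot(cmax > 0)
  known <- c("ICaL", "INaL", "INa", "Ito", "IKs", "IK1")
  bad <- setdiff(names(hill), known)
  if (length(bad)) stop("unknown current(s): ", paste(bad, collapse = ", "))
  structure(list(binding = binding, hill = hill, cmax = cmax,
                 index = as.integer(index), drug = drug),
            class = "drug_effect_sample")
}

# drug_effect (cell-model input) for a sample at a concentration
.effect_at <- function(sample, conc) {
  block <- vapply(c("INa", "INaL", "Ito", "ICaL", "IKs", "IK1"), function(cn) {
    hp <- sample$hill[[cn]]
    if (is.null(hp)) 0 else min(hill_block(hp, conc) / 100, 1)
  }, numeric(1))
  drug_effect(block = block, binding = sample$binding, conc = conc)
}

#' Simulate one drug-effect sample at a concentration multiple
#'
#' Initializes from the cached control steady state, paces with the sample's
#' drug effects at `multiple * cmax`, classifies the analyzed beats and
#' computes qNet on the selected beat.  A simulation is classified `EAD` if
#' any analyzed beat has an EAD, `depolarization_failure` if every analyzed
#' beat fails to depolarize (no qNet), and `normal` otherwise.
#'
#' @param sample A [drug_effect_sample()].
#' @param multiple Concentration multiple of `cmax`.
#' @param beats Paced beats (protocol default 1000; smaller values are
#'   scaled-down non-conformant runs for testing).
#' @param analysis_beats Trailing beats analyzed (default 250, capped at
#'   `beats`).
#' @param protocol Base [pacing_protocol()]; its `beats` is overridden.
#' @param scaling,config As in [run_pacing()].
#' @param rtol Solver relative tolerance (1e-6; 1e-3 for relaxed runs).
#' @param steady_state Optional precomputed control steady state.
#' @return A `simulation_result`: list with `drug`, `multiple`, `index`,
#'   `conc`, `classification`, `qnet`, `dvdt_repol_max`, `n_ead`,
#'   `n_depol_fail`, `beat_index`.
#' @export
run_drug_simulation <- function(sample, multiple, beats = 1000,
                                analysis_beats = 250,
                                protocol = pacing_protocol(),
                                scaling = conductance_scaling(),
                                config = .default_config(), rtol = NULL,
                                steady_state = NULL) {
  conc <- multiple * sample$cmax
  effect <- .effect_at(sample, conc)
  protocol$beats <- beats
  keep <- min(analysis_beats, beats)
  if (is.null(steady_state))
    steady_state <- control_steady_state(protocol = protocol,
                                         scaling = scaling, config = config)
  init <- steady_state
  init[["qNet"]] <- 0
  res <- run_pacing(init, protocol, scaling, effect, keep_beats = keep,
                    dt = 1, rtol = rtol, config = config)
  summaries <- lapply(res$beats, function(b) classify_beat(b$time_ms, b$Vm_mV))
  depol <- vapply(summaries, `[[`, logical(1), "depolarized")
  eads <- vapply(summaries, `[[`, logical(1), "ead")
  classification <- if (!any(depol)) "depolarization_failure"
    else if (any(eads)) "EAD" else "normal"
  qnet <- NA_real_
  bi <- NA_integer_
  dvmax <- NA_real_
  if (classification != "depolarization_failure") {
    bi <- select_qnet_beat(summaries)
    qnet <- compute_qnet(res$beats[[bi]], cl = protocol$cl)
    dvmax <- summaries[[bi]]$dvdt_repol
  }
  structure(list(drug = sample$drug, multiple = multiple,
                 index = sample$index, conc = conc,
                 classification = classification, qnet = qnet,
                 dvdt_repol_max = dvmax,
                 n_ead = sum(eads[depol]), n_depol_fail = sum(!depol),
                 beat_index = bi),
            class = "simulation_result")
}

#' Build paired drug-effect samples from uncertainty distributions
#'
#' Pairs the b-th bootstrap row of the hERG binding distribution with the
#' b-th MCMC draw of every non-hERG current's Hill chain (sequential-index
#' pairing; the source distributions are assumed independent).
#'
#' @param herg A [bootstrap_fit()] result (or a matrix of transformed
#'   binding parameters with the standard columns).
#' @param hills Named list over currents of [mcmc_hill()] chains (or `NULL`
#'   for a null effect).
#' @param cmax Maximum therapeutic concentration (nM).
#' @param n_samples Number of paired samples to form; all sources must have
#'   at least this many rows.
#' @param drug Drug name.
#' @return List of [drug_effect_sample()]s.
#' @export
pair_uncertainty_samples <- function(herg, hills = list(), cmax,
                                     n_samples = 2000, drug = "synthetic") {
  theta <- if (inherits(herg, "bootstrap_distribution")) herg$theta else herg
  if (nrow(theta) < n_samples)
    stop("binding distribution has ", nrow(theta), " rows; need ", n_samples)
  for (cn in names(hills)) {
    if (!is.null(hills[[cn]]) && nrow(hills[[cn]]$draws) < n_samples)
      stop("Hill chain for ", cn, " has fewer than ", n_samples, " draws")
  }
  lapply(seq_len(n_samples), function(b) {
    bp <- binding_from_log10(theta[b, "log10_Kmax"], theta[b, "log10_EC50n"],
                             theta[b, "n"], theta[b, "log10_Ku"],
                             theta[b, "Vhalftrap"])
    hp <- lapply(hills, function(ch) {
      if (is.null(ch)) return(NULL)
      hill_params(ch$draws[b, "pIC50"], ch$draws[b, "h"])
    })
    drug_effect_sample(bp, hp, cmax, index = b, drug = drug)
  })
}

#' Propagate drug-effect uncertainty to qNet distributions
#'
#' Runs [run_drug_simulation()] for every paired sample at every
#' concentration multiple.  Samples with complete depolarization failure are
#' excluded from the qNet vectors but counted; survivors + failures equal the
#' number of samples at every concentration.
#'
#' @param samples List of [drug_effect_sample()]s (see
#'   [pair_uncertainty_samples()]).
#' @param multiples Concentration multiples of cmax.
#' @param ... Passed to [run_drug_simulation()] (`beats`, `scaling`, `rtol`,
#'   ...).
#' @return A `qnet_distribution`: list with `drug`, `multiples`, and per
#'   multiple `qnet` (surviving samples' values), `ci` (95%), `n_ead`,
#'   `n_depol_fail`, `n_total`, plus `results` (flat list of
#'   simulation_result objects).
#' @export
propagate_uncertainty <- function(samples, multiples, ...) {
  stopifnot(length(samples) >= 1)
  drug <- samples[[1]]$drug
  per <- vector("list", length(multiples))
  names(per) <- as.character(multiples)
  results <- list()
  for (mi in seq_along(multiples)) {
    m <- multiples[mi]
    res <- lapply(samples, run_drug_simulation, multiple = m, ...)
    results <- c(results, res)
    qn <- vapply(res, `[[`, numeric(1), "qnet")
    cls <- vapply(res, `[[`, character(1), "classification")
    surv <- cls != "depolarization_failure"
    per[[mi]] <- list(
      qnet = qn[surv],
      ci = if (any(surv)) credible_interval(qn[surv]) else c(lo = NA, hi = NA),
      n_ead = sum(cls == "EAD"),
      n_depol_fail = sum(!surv),
      n_total = length(samples))
  }
  structure(list(drug = drug, multiples = multiples, per_multiple = per,
                 results = results),
            class = "qnet_distribution")
}
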