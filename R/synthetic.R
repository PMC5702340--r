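# Synthetic-data generators with known ground truth.  They emulate the two
# experimental input kinds -- Milnes-protocol fractional hERG current traces
# (one concentration per cell, per-cell multiplicative scale plus additive
# Gaussian noise) and Hill dose-response percent-block points (Gaussian
# observation noise) -- with the statistical structure the analysis assumes.
# All generators are pure functions of (spec, seed).

#' Synthetic drug specification
#'
#' @param name Drug name.
#' @param binding Ground-truth [drug_binding_params()].
#' @param hill Named list (over `ICaL, INaL, INa, Ito, IKs, IK1`) of
#'   ground-truth [hill_params()] or `NULL` entries (null effect).
#' @param cmax Synthetic maximum therapeutic concentration (nM).
#' @param milnes_conc Concentrations (nM) tested in the Milnes assay; the
#'   default spans 0.5-3x cmax, emulating the experimental-design limitation
#'   that concentrations rarely exceed a few multiples of cmax.
#' @param cells_per_conc Cells per Milnes concentration.
#' @param dr_conc Concentrations (nM) tested in the dose-response assay.
#' @param dr_replicates Replicates per dose-response concentration.
#' @param trace_sd Additive Gaussian noise SD on fractional current (default 0.03, typical of averaged patch-clamp fractional currents).
#' @param cell_scale_sd SD of the per-cell multiplicative scale (mean 1).
#' @param dr_sd Gaussian noise SD on percent block.
#' @param category True TdP risk category (0/1/2) when the spec belongs to a
#'   labelled panel, else `NA`.
#' @return A `synthetic_drug_spec`.
#' @export
synthetic_drug_spec <- function(name, binding, hill = list(), cmax,
                                milnes_conc = c(0.5, 1, 2, 3) * cmax,
                                cells_per_conc = 6,
                                dr_conc = c(0.5, 1, 2, 3) * cmax,
                                dr_replicates = 4,
                                trace_sd = 0.03, cell_scale_sd = 0.03,
                                dr_sd = 5, category = NA_integer_) {
  stopifnot(cmax > 0, all(milnes_conc > 0), all(dr_conc > 0),
            cells_per_conc >= 1, dr_replicates >= 1,
            trace_sd >= 0, cell_scale_sd >= 0, dr_sd >= 0)
  structure(list(name = name, binding = binding, hill = hill, cmax = cmax,
                 milnes_conc = milnes_conc, cells_per_conc = cells_per_conc,
                 dr_conc = dr_conc, dr_replicates = dr_replicates,
                 trace_sd = trace_sd, cell_scale_sd = cell_scale_sd,
                 dr_sd = dr_sd, category = category),
            class = "synthetic_drug_spec")
}

#' Generate a synthetic Milnes trace dataset
#'
#' Simulates the ground-truth fractional current at each tested
#' concentration, then emits per-cell traces
#' `truth * cell_scale * (1 + additive noise)`, one concentration per cell.
#'
#' @param spec A [synthetic_drug_spec()].
#' @param seed Integer seed.
#' @param protocol [milnes_protocol()].
#' @param config Model configuration.
#' @return A [trace_dataset()].
#' @export
make_synthetic_milnes <- function(spec, seed, protocol = milnes_protocol(),
                                  config = .default_config()) {
  control <- .milnes_open_prob(spec$binding, protocol, 0, config)
  truth <- lapply(spec$milnes_conc, function(cc)
    simulate_milnes(spec$binding, protocol, cc, config, control = control)$frac)
  set.seed(seed)
  traces <- list()
  conc <- numeric(0)
  for (k in seq_along(spec$milnes_conc)) {
    for (i in seq_len(spec$cells_per_conc)) {
      scale <- 1 + stats::rnorm(1, 0, spec$cell_scale_sd)
      noise <- matrix(stats::rnorm(length(truth[[k]]), 0, spec$trace_sd),
                      nrow(truth[[k]]), ncol(truth[[k]]))
      traces[[length(traces) + 1]] <- truth[[k]] * scale * (1 + noise)
      conc <- c(conc, spec$milnes_conc[k])
    }
  }
  trace_dataset(traces, conc, control$time_ms, drug = spec$name)
}

#' Generate synthetic dose-response points for one current
#'
#' `block = hill_block(truth, D) + N(0, dr_sd)` per replicate.
#'
#' @param spec A [synthetic_drug_spec()]; its `hill` entry for `current` must
#'   be non-null.
#' @param current Current name.
#' @param seed Integer seed.
#' @return data.frame from [dose_response_points()].
#' @export
make_synthetic_doseresponse <- function(spec, current, seed) {
  hp <- spec$hill[[current]]
  if (is.null(hp))
    stop("spec has a null effect for ", current,
         "; no dose-response data to generate")
  set.seed(seed)
  conc <- rep(spec$dr_conc, each = spec$dr_replicates)
  block <- hill_block(hp, conc) + stats::rnorm(length(conc), 0, spec$dr_sd)
  dose_response_points(conc, block,
                       replicate = rep(seq_len(spec$dr_replicates),
                                       times = length(spec$dr_conc)))
}

#' Synthetic uncertainty distributions around a spec's ground truth
#'
#' Produces binding-parameter samples and Hill chains with the same structure
#' as [bootstrap_fit()] / [mcmc_hill()] outputs, drawn around the
#' ground-truth values with controllable spread.  Used to exercise
#' uncertainty propagation at scales where running the full fitting chain for
#' every drug would dominate the cost of the experiment being studied.
#'
#' @param spec A [synthetic_drug_spec()].
#' @param n Number of samples/draws.
#' @param seed Integer seed.
#' @param binding_sd SD of the jitter on the transformed binding parameters
#'   `(log10 Kmax, log10 EC50n, n, log10 Ku, Vhalftrap)` (recycled).
#' @param hill_sd SD of the jitter on `(pIC50, h)` (recycled).
#' @return List with `herg` (n x 5 matrix, standard columns) and `hills`
#'   (named list of `mcmc_chain`-shaped objects or `NULL`).
#' @export
synthetic_uncertainty_inputs <- function(spec, n, seed,
                                         binding_sd = c(0.05, 0.05, 0.01,
                                                        0.02, 1),
                                         hill_sd = c(0.03, 0.03)) {
  set.seed(seed)
  binding_sd <- rep_len(binding_sd, 5)
  hill_sd <- rep_len(hill_sd, 2)
  th0 <- c(log10(max(spec$binding$Kmax, 1e-12)), log10(spec$binding$EC50n),
           spec$binding$n, log10(spec$binding$Ku), spec$binding$Vhalftrap)
  theta <- t(replicate(n, th0 + stats::rnorm(5, 0, binding_sd)))
  colnames(theta) <- .binding_par_names
  if (spec$binding$Kmax == 0) theta[, "log10_Kmax"] <- -Inf
  hills <- lapply(stats::setNames(nm = c("ICaL", "INaL", "INa", "Ito",
                                         "IKs", "IK1")), function(cn) {
    hp <- spec$hill[[cn]]
    if (is.null(hp)) return(NULL)
    draws <- cbind(pIC50 = hp$pIC50 + stats::rnorm(n, 0, hill_sd[1]),
                   h = pmax(hp$h + stats::rnorm(n, 0, hill_sd[2]), 0.01))
    structure(list(draws = draws, sigma2 = rep(NA_real_, n),
                   acceptance = NA_real_, seed = seed, n_saved = n),
              class = "mcmc_chain")
  })
  hills <- hills[!vapply(hills, is.null, logical(1))]
  list(herg = theta, hills = hills)
}

#' Built-in synthetic drug panels
#'
#' * `training12-like`: 12 specs whose binding and Hill ground truths are the
#'   published optimal estimates for the CiPA training compounds; the
#'   synthetic cmax values are chosen so tested concentrations span 0.5-3x
#'   cmax (the cmax values are NOT the clinical ones, which live in
#'   supplementary material elsewhere).
#' * `separable9`: three drugs per risk category with engineered qNet
#'   separation (graded hERG binding strength and trapping).
#' * `null`: three no-block drugs (control behaviour).
#'
#' @param name Panel name.
#' @return Named list of [synthetic_drug_spec()]s.
#' @export
fixture_panel <- function(name = c("training12-like", "separable9", "null")) {
  name <- match.arg(name)
  if (name == "training12-like") {
    bt <- herg_binding_table()
    ht <- hill_parameter_table()
    labs <- risk_labels()
    specs <- lapply(seq_len(nrow(bt)), function(i) {
      b <- bt[i, ]
      bp <- binding_from_log10(b$log10_Kmax, b$log10_EC50n, b$n, b$log10_Ku,
                               b$Vhalftrap)
      # synthetic cmax: concentration at which the binding multiplier equals
      # 1 (on-rate = Ku) -- inside the near-linear regime for these drugs
      cmax <- (bp$EC50n / max(bp$Kmax - 1, 1e-6))^(1 / bp$n)
      hh <- ht[ht$drug == b$drug, ]
      hill <- stats::setNames(lapply(hh$current, function(cn) {
        r <- hh[hh$current == cn, ]
        if (is.na(r$pIC50)) NULL else hill_params(r$pIC50, r$h)
      }), hh$current)
      synthetic_drug_spec(b$drug, bp, hill, cmax = cmax,
                          category = labs$category[labs$drug == b$drug])
    })
    names(specs) <- bt$drug
    return(specs)
  }
  if (name == "separable9") {
    # graded pure-hERG blockers: binding multiplier at cmax ~ 0 (Low),
    # moderate (Intermediate), strong (High); High-risk drugs are trapped
    # (Vhalftrap near -1 mV), Low-risk untrapped.
    cmax <- 100
    mk <- function(nm, ratio, vhalf, cat)
      synthetic_drug_spec(nm,
        binding_from_log10(log10_Kmax = 6, log10_EC50n = 6 - log10(ratio),
                           n = 1, log10_Ku = -3, Vhalftrap = vhalf),
        hill = list(), cmax = cmax, category = cat)
    specs <- c(
      lapply(1:3, function(i) mk(paste0("low", i), 1e-4 / (100 * cmax),
                                 -95 - 5 * i, 0L)),
      lapply(1:3, function(i) mk(paste0("int", i), (3.6 + 0.4 * i) / cmax,
                                 -85, 1L)),
      lapply(1:3, function(i) mk(paste0("high", i), (14 + 2 * i) / cmax,
                                 -1, 2L)))
    names(specs) <- vapply(specs, `[[`, character(1), "name")
    return(specs)
  }
  # null panel
  specs <- lapply(1:3, function(i)
    synthetic_drug_spec(paste0("null", i),
                        drug_binding_params(Kmax = 0, EC50n = 1, n = 1,
                                            Ku = 1e-3, Vhalftrap = -100),
                        hill = list(), cmax = 100, category = 0L))
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  specs
}
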