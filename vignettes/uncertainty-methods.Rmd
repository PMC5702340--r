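---
title: "Uncertainty quantification for qNet-based proarrhythmia risk: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Uncertainty quantification for qNet-based proarrhythmia risk: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

The CiPA (Comprehensive in vitro Proarrhythmia Assay) paradigm assesses a
drug's Torsade-de-Pointes (TdP) liability by feeding in-vitro ion-channel
pharmacology into an in-silico model of the human ventricular action
potential and summarizing the result as **qNet** — the net charge carried by
the six major currents (IKr, ICaL, INaL, Ito, IKs, IK1) over one paced beat,
in µC/µF. Drug effects are estimated from noisy experiments, so any risk call
derived from qNet inherits that noise. This package implements the full
uncertainty-quantification chain: estimate the joint sampling distributions
of the drug-effect parameters, push them through the action-potential model
to a distribution of qNet per drug and concentration, and quantify how robust
ordinal risk stratification is to that uncertainty.

## Model components

### Action potential model

`run_pacing()` integrates the CiPAORdv1.0 ventricular cell: the O'Hara–Rudy
(2011) endocardial formulation with the hERG current replaced by a 9-state
Markov model with dynamic drug binding and trapping (Li et al. 2017
topology), and maximal conductances rescaled by the Dutta et al. (2017)
optimized factors (INaL ×2.661, ICaL ×1.007, IKr ×1.013, IKs ×1.870,
IK1 ×1.698). The right-hand side is compiled C integrated with
`deSolve::lsoda` at relative/absolute tolerances of 1e-6 (a relaxed 1e-3
relative tolerance is available for bootstrap-refit workloads). Pacing is at
a cycle length of 2 s with a −80 µA/µF, 0.5 ms stimulus applied as a
depolarizing current; a unit test asserts the first beat depolarizes above
0 mV. The qNet accumulator is itself a state variable, so qNet comes from
the solver at solver accuracy; `qnet_trapz()` provides an independent
trapezoid cross-check on the logged currents.

All constants live in `inst/extdata/cipaordv1.yaml`, a versioned text file
with a provenance block. One deliberate divergence is documented there: the
voltage-dependent gating constants of the hERG Markov model are published
only in supplementary material of the companion papers, so this package maps
the well-characterized Wang et al. (1997) hERG gating kinetics
(temperature-adjusted to 37 °C) onto the Li et al. state topology, with
state-independent inactivation so every loop satisfies detailed balance. The
binding layer — on-rate `Ku · Kmax·Dⁿ/(Dⁿ + EC50ⁿ)` to the open and
inactivated-open states, unbinding at `Ku` with a microscopic-reversibility
correction for the inactivated-bound state, and trapping transitions at
`Kt = 3.5e-5 ms⁻¹` gated by a sigmoid of slope 6.789 mV around `Vhalftrap` —
follows the deposited structure exactly. Consequences: the package's
absolute qNet values are its own, not those of the deposited implementation;
every relationship the pipeline studies (binding identifiability, EAD
induction by strong hERG block, qNet monotonicity, risk separation) is
preserved.

### Steady state

`control_steady_state()` paces from the published O'Hara–Rudy initial
conditions until the maximum relative change of any state component between
consecutive cycle starts drops below 1e-6 (about 630 beats at CL 2 s),
rather than hardcoding a steady-state table; the fixed-point property is
unit-tested. The result is cached per session and optionally to a file. All
drug simulations start from this control steady state.

### hERG binding kinetics and the bootstrap

Milnes-protocol voltage-clamp simulation exploits the fact that a
piecewise-constant clamp makes the bound Markov model linear time-invariant
within each segment: segments are propagated by matrix exponentials
(eigendecomposition with an `expm` stepping fallback), which is exact and
fast enough to sit inside a bootstrap-of-CMA-ES loop. The default protocol
(950 ms hold at −80 mV, 10 s measurement step at 0 mV, 14.05 s recovery;
10 sweeps) is configuration data. Fractional current is the drug/control
open-probability ratio on the measurement step, resampled to a uniform grid
(10 ms by default; fitting fixtures use 100 ms, which loses nothing because
the propagation is exact on any grid).

`fit_cmaes()` minimizes the sum of squared differences between predicted and
mean observed fractional currents over all concentrations, sweeps and grid
points. The five free parameters are fitted in transformed space — log10 for
Kmax, EC50ⁿ and Ku, linear for n and Vhalftrap — inside box bounds
(log10 Kmax, log10 EC50ⁿ ∈ [0, 9]; n ∈ [0.3, 2]; log10 Ku ∈ [−5, 0];
Vhalftrap ∈ [−200, −1] mV; the published per-drug estimates all fall inside
these). The original bounds table is supplementary material and not
reproduced; these are the package's defaults and are configurable. CMA-ES
itself (`cma_es()`) is a from-scratch (µ/µ_w, λ) implementation with
cumulative step-size adaptation and rank-1 + rank-µ covariance updates; the
search runs in normalized [0, 1]⁵ coordinates because the raw parameter
scales differ by two orders of magnitude. The initial mean is evaluated so a
warm-started search can never end worse than its start.

`bootstrap_fit()` resamples cells with replacement independently within each
concentration (each cell is measured at a single concentration, so
concentrations are independent strata), recomputes the mean response and
refits. Replicate seeds derive from the master seed by a counter scheme.
Refits are warm-started at the full-data optimum with initial step 0.25 and a smaller generation cap: a resampled mean is a small
perturbation of the full-data mean, so the refit is a local correction, and
the warm start cuts the per-replicate cost several-fold without constraining
the ridge direction, along which the objective is flat. Failed replicates
are dropped and counted, never imputed.

The scientifically important behaviour reproduced here is the
**identifiability collapse**: when EC50ⁿ is far above every tested
concentration, the Emax binding term is effectively `(Kmax/EC50ⁿ)·Dⁿ`, so
only the ratio is identifiable. Bootstrap distributions then show a tight
ridge — log10 Kmax and log10 EC50ⁿ each spanning orders of magnitude with
correlation near 1 — while their difference and Ku stay well constrained.

### Hill dose-response and DRAM

The six non-hERG currents use a pore-block model: conductance scaled by
`1 − block/100` with `block = 100·Dʰ/(Dʰ + IC50ʰ)`, `pIC50 = −log10(IC50/c0)`,
`c0 = 1e9 nM`. `fit_hill_nls()` is deterministic multi-start bounded least
squares on (pIC50 ∈ [−1, 19], h ∈ [0, 10]). Data whose maximum mean observed
block is below 20% cannot bracket the IC50 and are flagged `unconstrained`
(the threshold is configurable; the flag is descriptive, the fit is still
returned). Drug–current pairs with no measurable block carry a null effect —
0% block at every concentration — and are excluded from MCMC.

`mcmc_hill()` samples the posterior of (pIC50, h) under a Gaussian
observation model with unknown variance σ²: uniform prior over the bounds
box, conjugate inverse-gamma Gibbs updates for σ² (prior shape
`0.5·n_obs·w` with weight `w = 0.1`, centred on the NLS residual variance —
vague, and dominated by the data once a handful of points exist), adaptive
Metropolis with one delayed-rejection stage (proposal shrunk ×0.25), and a
global proposal scale adapted toward 35% acceptance. Burn-in is 10,000
iterations and draws are thinned (default 5) so exactly `n_saved` (default
2,000) are kept; only the saved count is prescribed by the assay convention,
the rest are this package's defaults. Chains are seed-deterministic.

Two regimes matter. With well-constrained data (block spanning well past
50%), the posterior is a tight unimodal peak and the 95% block interval
stays narrow even at 10× the highest tested concentration (Chigh). With
truncated data (max block ≈ 12%), draws spread to the imposed bounds, h and
IC50 trade off along an inverse ridge (equivalently a *positive* pIC50–h
association, since pIC50 = −log10 IC50), and the predicted-block interval
approaches the full 0–100% range a decade above Chigh.
`extrapolation_uncertainty()` quantifies this and flags extrapolation
`reliable` only when observed mean block at Chigh exceeds 60% — the
operational "60% rule" for trusting dose-response extrapolation.

### Propagation and risk stratification

`pair_uncertainty_samples()` pairs the b-th bootstrap row with the b-th MCMC
draw of every current (sequential-index pairing; the sources are independent
by construction). `run_drug_simulation()` paces each paired sample from the
control steady state, classifies the analyzed beats (`classify_beat()`:
depolarized iff Vm exceeds 0 mV; repolarization levels measured from the
takeoff potential at stimulus onset, which is well defined on every beat
including abnormal ones; dV/dt_repol by central differences on a 1 ms grid
over the three-case window — 30–90% repolarization, 30%–end, or peak–end;
EAD iff dV/dt_repol > 0), and takes qNet from the depolarized beat with
maximum dV/dt_repol (earliest on ties). A simulation with an EAD on any
analyzed beat is an EAD simulation; one where every beat fails to depolarize
is a depolarization failure and contributes no qNet but stays in the
accounting (survivors + failures = samples, asserted). Each concentration
restarts from the control steady state rather than chaining concentrations;
restarting is reproducible and order-independent, and it matches
initializing every simulation from control.

`fit_proportional_odds()` is a maximum-likelihood cumulative-logit fit
(analytic gradient, BFGS, relative tolerance 1e-10, generous iteration cap;
quasi-complete separation is cap-and-warn, not penalized). Categories are
0 = Low, 1 = Intermediate, 2 = High. `loocv()` leaves one drug out, trains on
the pooled samples of the rest (unweighted pooling across drugs with unequal
surviving counts — a documented choice), assigns each left-out sample to its
argmax category (ties to the lower category, for determinism), and reports
per-category fractions P(x) and the error `Σ P(x)·|x − c|`.
`current_knockout_loocv()` re-propagates with one current's drug effects
removed (Hill component dropped, or the hERG binding multiplier zeroed for
IKr) to measure how much stratification depends on that current.

## Synthetic data: what it emulates, and what it does not

`make_synthetic_milnes()` emits per-cell traces
`truth × cell_scale × (1 + ε)` with `cell_scale ~ N(1, 0.03)` and
`ε ~ N(0, 0.03)` pointwise, one concentration per cell (defaults: 6 cells
per concentration, 4 concentrations spanning 0.5–3× cmax — mirroring the
experimental-design reality that tested concentrations rarely exceed a few
multiples of the therapeutic maximum, which is exactly what drives
extrapolation uncertainty). `make_synthetic_doseresponse()` adds N(0, 5%)
noise to the true Hill curve, 4 replicates per concentration. Noise is
applied to the fractional current, not the raw current, because that is what
the pipeline consumes. The generators are pure functions of (spec, seed).

Not emulated: instrument artifacts (rundown, leak, series-resistance error),
inter-cell kinetic variability (a hierarchical structure the population-mean
bootstrap deliberately does not model), temperature drift, and any
between-lab effects. Passing tests on this synthetic data therefore
demonstrate correctness of the estimation and propagation machinery under
the stated noise model — not that real experimental variability is fully
captured by it.

Panels: `training12-like` uses the published optimal binding/Hill estimates
for the 12 CiPA training compounds as ground truth (with synthetic cmax
values — the clinical ones are supplementary data elsewhere and not shipped);
`separable9` engineers three drugs per risk category whose qNet
distributions separate cleanly through graded hERG block and trapping (Low:
no block; Intermediate: moderate untrapped block; High: strong trapped
block, EAD-prone); `null` is the no-effect control panel.
`synthetic_uncertainty_inputs()` generates ground-truth-centred parameter
distributions shaped like `bootstrap_fit()`/`mcmc_hill()` output, so
propagation and LOOCV can be exercised without paying for a full fitting
chain per drug in every test run.

## Numerical choices and problem sizes

* Solver: lsoda, rtol = atol = 1e-6; per-beat restart at the stimulus
  discontinuity; dense output at 1 ms for classification (the accumulator,
  not the grid, determines qNet). The accumulator-vs-trapezoid check uses a
  0.05 ms grid because the trapezoid rule, not the solver, limits agreement
  on the stiff upstroke.
* Steady state: tolerance 1e-6 on the max relative per-beat state change,
  cap 1,500 beats (reached in ~630).
* CMA-ES: λ = 8 for 5 parameters, initial σ = 0.25 in normalized
  coordinates, 250 generations + 1 restart for full fits; bootstrap refits
  are warm-started with σ = 0.25 and 80 generations (enough exploration
  that replicate fits traverse the flat identifiability ridge; smaller caps
  understate its spread).
* DRAM: burn-in 10,000, thin 5, adaptation every 100 iterations, DR scale
  0.25, target acceptance 0.35.
* Reduced-scale study sizes used by the test suite and the acceptance
  script, chosen so the full chain runs comfortably on a single CPU:
  bootstrap B = 100 (headline ridge analysis), MCMC 2,000 saved draws,
  propagation 6 paired samples per drug over 9 drugs at 30 beats per
  simulation with the last 10 analyzed. Production-scale settings (B =
  2,000 bootstrap replicates, 2,000 saved draws, 2,000 paired samples, 1,000
  beats, last 250 analyzed) remain the documented defaults of the
  corresponding functions. At 30 beats the drug-bound state has not fully
  equilibrated, so short runs understate block depth for slowly-binding,
  strongly-trapped compounds; the separable panel is engineered so category
  gaps dwarf this effect.

## Degenerate inputs and edge rules

Zero concentration returns unit fractional current and reproduces control
behaviour regardless of which drug's binding parameters are attached (tested
as an invariant). Occupancy conservation is enforced (hard error beyond
1e-4 drift; the exact propagator keeps it near machine precision). Beats
that never cross 0 mV are excluded from EAD evaluation; a simulation where
all beats fail contributes to the failure count only. Ties in beat selection
go to the earliest beat; ties in category assignment to the lower category.
All-zero dose-response data yield a boundary NLS fit flagged
`unconstrained`. Empty samples are an error for `credible_interval()`.

## Known limitations

* The hERG gating constants are a documented stand-in calibration (see the
  parameter-file provenance block): absolute qNet values and EAD thresholds
  differ from the deposited CiPAORdv1.0 implementation, so published per-drug
  qNet tables cannot be compared number-for-number without swapping in the
  deposited constants (the YAML makes that a data edit, not a code change).
* Population-mean fitting: inter-cell kinetic variability is treated as
  noise around a mean response, not modelled hierarchically.
* The proportional-odds classifier assumes a common slope across category
  thresholds; with heavily overlapping qNet distributions the cap-and-warn
  behaviour under separation is the only safeguard.
* Endocardial cells only; no tissue-level or transmural simulation.
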