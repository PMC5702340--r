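# CiPAORdv1.0 model parameter file (version 1).
#
# Provenance: the base action-potential equations and constants follow the
# O'Hara-Rudy (2011) endocardial formulation; the IKr Markov scheme with
# dynamic drug binding and trapping follows Li et al. (2017, Circ Arrhythm
# Electrophysiol); the conductance scaling factors are the Dutta et al. (2017,
# Front Physiol) AP-duration-optimized values.  Constants below were
# transcribed from those companion publications and the FDA CiPA deposited
# implementation; any divergence from the deposited CiPAORdv1.0 tables should
# be flagged against this block.
version: 1
celltype: endo

physical:
  nao: 140.0      # mM
  cao: 1.8        # mM
  ko: 5.4         # mM
  Rgas: 8314.0    # J/kmol/K
  Temp: 310.0     # K
  Frdy: 96485.0   # C/mol

# Base maximal conductances / permeabilities (endocardial O'Hara-Rudy values).
conductances:
  GNa: 75.0
  GNaL: 0.0075
  Gto: 0.02
  PCa: 0.0001
  GKr: 0.046
  GKs: 0.0034
  GK1: 0.1908
  Gncx: 0.0008
  Pnak: 30.0
  GKb: 0.003
  PNab: 3.75e-10
  PCab: 2.5e-8
  GpCa: 0.0005

# Dutta et al. optimized multiplicative scalings (CiPAORdv1.0).  Identity
# scaling (all 1) recovers the unscaled IKr-dynamic ORd model.
scaling:
  INaL: 2.661
  ICaL: 1.007
  IKr: 1.013
  IKs: 1.870
  IK1: 1.698
  Ito: 1.0
  INa: 1.0

# IKr Markov model: 6 drug-free states (IC1, IC2, C1, C2, O, IO) + 3
# drug-bound states (IObound, Obound, Cbound), following the Li et al. (2017)
# state topology, Emax drug binding, trapping and microscopic-reversibility
# structure.  Provenance note: the Li et al. voltage-dependent gating
# constants themselves are published only in supplementary material / the
# deposited FDA implementation and are NOT reproduced here; the transition
# rates below are adapted from the Wang et al. (1997, J Physiol) hERG gating
# kinetics (activation, deactivation, fast inactivation), temperature-scaled
# to 37 C (Q10 ~ 2.5), mapped onto the Li topology with state-independent
# inactivation so that all loops satisfy detailed balance.  This is a
# divergence from the deposited CiPAORdv1.0 gating numbers and is flagged
# here as such; the binding/trapping parameterization (Kmax, EC50^n, n, Ku,
# Vhalftrap, Kt) is unchanged in form.
# Transition rate i -> j is A*exp(B*V) * q^((Temp_C-20)/10) with Temp_C = 37.
ikr_markov:
  temp_c: 37.0
  rates:
    A1:  {A: 0.022348, B: 0.01176,   q: 1.0}   # C1 -> C2  (activation step 1)
    A2:  {A: 0.047002, B: -0.0631,   q: 1.0}   # C2 -> C1
    A3:  {A: 0.0549,   B: 0.038198,  q: 1.0}   # IC2 -> IO (activation, inact. tier)
    A4:  {A: 2.76e-4,  B: -0.04178,  q: 1.0}   # IO -> IC2
    A11: {A: 0.022348, B: 0.01176,   q: 1.0}   # IC1 -> IC2
    A21: {A: 0.047002, B: -0.0631,   q: 1.0}   # IC2 -> IC1
    A31: {A: 0.0549,   B: 0.038198,  q: 1.0}   # C2 -> O   (activation step 2)
    A41: {A: 2.76e-4,  B: -0.04178,  q: 1.0}   # O -> C2   (deactivation)
    A51: {A: 0.4083,   B: 0.023391,  q: 1.0}   # C1 -> IC1 (inactivation)
    A61: {A: 0.02207,  B: -0.03268,  q: 1.0}   # IC1 -> C1 (recovery)
    A52: {A: 0.4083,   B: 0.023391,  q: 1.0}   # C2 -> IC2
    A62: {A: 0.02207,  B: -0.03268,  q: 1.0}   # IC2 -> C2
    A53: {A: 0.4083,   B: 0.023391,  q: 1.0}   # O -> IO   (fast inactivation)
    A63: {A: 0.02207,  B: -0.03268,  q: 1.0}   # IO -> O   (recovery)
  # Drug trapping: Obound/Cbound and IObound/Cbound transitions run at rate
  # Kt, gated by a sigmoid in Vm with half-potential Vhalftrap and slope k.
  trapping:
    Kt: 3.5e-5         # ms^-1, fixed
    slope_mV: 6.789    # mV, deposited-implementation constant

# Modified Milnes voltage-clamp protocol used for hERG binding kinetics.
# The 0 mV step is the measurement segment; fractional current is the
# drug/control open-probability ratio on that segment.
milnes_protocol:
  sweeps: 10
  segments:
    - {voltage_mV: -80.0, duration_ms: 950.0,   measure: false}
    - {voltage_mV: 0.0,   duration_ms: 10000.0, measure: true}
    - {voltage_mV: -80.0, duration_ms: 14050.0, measure: false}
  grid_ms: 10.0

# Default pacing protocol for TdP risk evaluation.
pacing:
  cl_ms: 2000.0
  stim_amp: -80.0     # uA/uF, applied as depolarizing current
  stim_dur_ms: 0.5
  beats: 1000
  analysis_beats: 250

solver:
  rtol: 1.0e-6
  atol: 1.0e-6
  rtol_relaxed: 1.0e-3   # for bootstrap-refit simulations

# CMA-ES box bounds for the five free hERG binding parameters, in the fitting
# transform (log10 for Kmax, EC50^n, Ku; linear for n and Vhalftrap).
binding_bounds:
  log10_Kmax:   [0.0, 9.0]
  log10_EC50n:  [0.0, 9.0]
  "n":          [0.3, 2.0]
  log10_Ku:     [-5.0, 0.0]
  Vhalftrap:    [-200.0, -1.0]

# Hill-fit bounds (pIC50 with c0 = 1e9 nM; h dimensionless).
hill_bounds:
  pIC50: [-1.0, 19.0]
  h:     [0.0, 10.0]

# O'Hara-Rudy published endocardial initial conditions (model-definition data,
# used as the starting point for pacing-to-convergence; not a steady state of
# the paced CiPAORdv1.0 model).
initial_state:
  V: -87.5
  nai: 7.0
  nass: 7.0
  ki: 145.0
  kss: 145.0
  cai: 1.0e-4
  cass: 1.0e-4
  cansr: 1.2
  cajsr: 1.2
  m: 0.0
  hf: 1.0
  hs: 1.0
  j: 1.0
  hsp: 1.0
  jp: 1.0
  mL: 0.0
  hL: 1.0
  hLp: 1.0
  a: 0.0
  iF: 1.0
  iS: 1.0
  ap: 0.0
  iFp: 1.0
  iSp: 1.0
  d: 0.0
  ff: 1.0
  fs: 1.0
  fcaf: 1.0
  fcas: 1.0
  jca: 1.0
  nca: 0.0
  ffp: 1.0
  fcafp: 1.0
  xs1: 0.0
  xs2: 0.0
  xk1: 1.0
  Jrelnp: 0.0
  Jrelp: 0.0
  CaMKt: 0.0
  # IKr Markov occupancies (sum to 1; start in the deep closed state)
  IC1: 0.0
  IC2: 0.0
  C1: 1.0
  C2: 0.0
  O: 0.0
  IO: 0.0
  IObound: 0.0
  Obound: 0.0
  Cbound: 0.0
  qNet: 0.0
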