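Package: qnetuq
Title: Uncertainty Quantification for the CiPA In Silico Proarrhythmia Assay
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates and propagates uncertainty in drug effects through the
    CiPA (Comprehensive in vitro Proarrhythmia Assay) in silico pipeline. The
    package implements the CiPAORdv1.0 human ventricular action potential model
    (O'Hara-Rudy endocardial cell with a dynamic hERG Markov drug-binding model
    and optimized conductance scalings), CMA-ES fitting of hERG binding kinetics
    to Milnes-protocol fractional current traces with non-parametric bootstrap
    uncertainty, Bayesian delayed-rejection adaptive Metropolis sampling of Hill
    dose-response parameters for six further cardiac currents, propagation of
    paired uncertainty samples to distributions of the qNet torsade-de-pointes
    risk metric, and leave-one-out cross-validated proportional-odds risk
    stratification with current-knockout sensitivity analysis. Synthetic-data
    generators with known ground truth make every pipeline stage testable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    Matrix,
    stats,
    utils,
    yaml,
    jsonlite,
    tools
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
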