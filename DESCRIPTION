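Package: egfrsig
Title: Mechanistic Modeling of EGFR Pathway Signaling and Cetuximab Response
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ordinary-differential-equation modeling of EGFR/RAS-MAPK/PI3K-AKT
    signaling in gastric cancer cell lines under EGF and cetuximab treatment,
    with mutant-MET and mutant-PI3K structural variants. Provides steady-state
    pre-equilibration, forward-sensitivity simulation, an immunoblot observation
    model with per-gel scaling factors, maximum-likelihood estimation by
    multi-start trust-region optimization in log10 parameter space, AIC-based
    selection over cell-line-specificity hypotheses, Fisher-information and
    profile-likelihood uncertainty analysis, and in-silico perturbation
    experiments (knockdowns, MET inhibition, alternative ligands). Includes a
    synthetic-data generator emulating immunoblot time-course and dose-response
    designs for recovery and identifiability studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    minpack.lm,
    lhs,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
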