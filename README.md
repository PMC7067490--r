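# egfrsig

Mechanistic modeling of EGFR / RAS-MAPK / PI3K-AKT signaling in gastric
cancer cell lines under EGF and cetuximab treatment, for systems biologists
who want a complete, tested maximum-likelihood workflow around a signaling
ODE model: simulation with steady-state pre-equilibration and forward
sensitivities, an immunoblot observation model with per-gel scaling factors,
multi-start trust-region estimation, AIC-based model selection over
cell-line-specificity hypotheses, Fisher-information and profile-likelihood
uncertainty analysis, and in-silico perturbation experiments (knockdowns,
MET inhibition, alternative ligands).

## The model

States follow a mass-action reaction network,

    dx/dt = S v(x, θ),      x(0) = x₀(θ) (unperturbed steady state),

covering EGFR turnover (synthesis, degradation, ligand and competitive
cetuximab binding, dimerization/autophosphorylation, internalization,
degradation, recycling), lumped RAS→ERK and PI3K→AKT cascades, and two
structural variants: the constitutively active mutant MET receptor (MMET,
the cetuximab-resistance driver of Hs746T) and mutant PI3K p.E545K (a
receptor-independent activation term, carried by MKN1). Two cell lines and
two media share one base parameterization; differences enter as log-fold
changes, θ_Hs746T = exp(ξ)·θ_MKN1, with ξ fixed to zero for direct
biochemical interactions and free for lumped rates and expression levels
(media: expression only). Measurements are modeled as scaled observables
with additive Gaussian noise, y = s·h(x(t)) + ε, ε ~ N(0, σ²), and fitting
minimizes

    -log L = ½ Σ ((y − s·h)/σ)² + ½ Σ log(2π σ²)

by multi-start trust-region least squares in log10 parameter space. Model
variants are ranked by AIC = 2k + 2·(−log L) with ΔAIC = 10 as substantial
support loss; uncertainty comes from the FIM eigen-spectrum (sloppiness:
span > 10⁶) and profile likelihoods (90/95/99% intervals; practical
non-identifiability at significance 0.1).

Raw data for this design exist only as published figures, so the package
generates synthetic immunoblot datasets with known ground truth (the
`synthetic` module is first-class, tested code) and validates the entire
pipeline by recovery: parameters inside profile intervals, the true
specificity hypothesis winning the AIC race, identifiability responding to
the measured observables.

## Worked example

```r
library(egfrsig)

truth  <- default_truth(seed = 1)                    # turnover-only specificity
design <- pathway_design(cell_lines = "MKN1", egf_doses = NULL)
ds     <- generate_dataset(truth, design, noise = TRUE, seed = 101)

prob <- pathway_problem(ds,
                        free_kinetic = c("k_degR", "k_int", "k_rasE",
                                         "k_erkOff", "k_aktOff", "k_synR"),
                        profile_scalings = TRUE)
fit <- fit_pathway(prob, n_starts = 50, seed = 101)
fit
#> Multi-start pathway fit: 50 starts, 50 successful
#>   best -log L: -328.67043  | free parameters: 6
#>   plateau starts (margin 0.1): 48

coef(fit)[1:3]
#>     k_degR      k_int     k_rasE
#> 0.01053084 0.09826196 0.29802952

pr <- profile_likelihood(fit, "k_degR")
pr
#> Profile likelihood for k_degR (identifiable)
#>   level  lower  upper lower_finite upper_finite
#> 1  0.90 -2.037 -1.921         TRUE         TRUE
#> 2  0.95 -2.049 -1.910         TRUE         TRUE
#> 3  0.99 -2.073 -1.887         TRUE         TRUE
```

The fit lands on a reproducible plateau (48 of 50 starts within 0.1 of the
best objective); the best −log L of −328.7 sits in the noise-consistent band
around the σ-constant (−401.4 + ½·χ²₁₅₆); and the 95% profile interval for
the EGFR degradation rate, 10^[−2.049, −1.910] ≈ [0.0089, 0.0123] min⁻¹,
covers the generating truth of 0.01 min⁻¹. The same objects feed the rest of
the pipeline: `fit_hypotheses()` + `rank_models()` for the 8-model
specificity ensemble (on joint two-cell-line data, the turnover-only model
M5 attains ΔAIC = 0 while non-turnover models lose by hundreds of units),
`fim()`/`sloppiness()` for the eigen-spectrum, `simulate_met_inhibitor()`,
`simulate_areg()`, `apply_knockdown()` and `swap_pi3k_wildtype()` for the
prediction experiments, and `run_workflow()` to drive everything from a YAML
configuration.

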