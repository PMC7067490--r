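---
title: "Mechanistic modeling of EGFR signaling and cetuximab response"
author: "egfrsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanistic modeling of EGFR signaling and cetuximab response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(egfrsig)
```

## The biological question

Cetuximab is a monoclonal antibody that binds the epidermal growth factor
receptor (EGFR) and blocks ligand binding, shutting down RAS-MAPK and
PI3K-AKT signaling in cells that depend on receptor input. Gastric cancer
cell lines differ sharply in their response: MKN1 (which overexpresses EGFR
about 2.5-fold and carries the activating PI3K p.E545K mutation) responds to
cetuximab, while Hs746T (which carries a MET exon 14 juxtamembrane mutation
producing a constitutively active receptor, here called MMET) does not.
`egfrsig` implements a mechanistic ordinary-differential-equation (ODE) model
of this system together with the complete statistical workflow used to
interrogate it: maximum-likelihood estimation from immunoblot-style data,
model selection over cell-line-specificity hypotheses, identifiability
analysis, and in-silico perturbation experiments.

Because quantitative immunoblot data of this design are generally published
only as figures, the package ships a synthetic-data generator that emulates
the experimental design (time courses and dose responses, replicate gels,
per-gel scaling factors, additive Gaussian noise) with a known ground truth.
Every statistical claim the package makes is exercised against that known
truth.

## The model

States evolve as $\dot x = S\,v(x,\theta)$ with stoichiometric matrix $S$ and
mass-action fluxes $v$. The reaction set is the smallest network that
reproduces the qualitative biology:

* **EGFR turnover** — synthesis ($k_{synR}$), degradation ($k_{degR}$),
  ligand binding ($k_{onL}/k_{offL}$), competitive cetuximab binding
  ($k_{onC}/k_{offC}$; the antibody-bound receptor is signaling-inert),
  dimerization plus autophosphorylation lumped into one second-order step
  ($k_{dim}$), internalization ($k_{int}$), lysosomal degradation
  ($k_{degpD}$) and recycling with ligand loss ($k_{rec}$). Phospho-dimers
  carry two receptor units in the mass balance.
* **RAS-MAPK** — RAS activation by membrane-bound and internalized
  phospho-receptor (equal weight) and by pMMET; ERK phosphorylation lumped
  over RAF/MEK. An optional negative feedback from pERK to active RAS is a
  structural variant flag.
* **PI3K-AKT** — PI3K activation by the same receptor inputs; the p.E545K
  mutant adds a receptor-independent activation term ($k_{pi3kMut}$), which
  is what renders pAKT cetuximab-insensitive in MKN1.
* **Mutant MET** — synthesized and degraded, constitutively cycling between
  MMET and pMMET ($k_{metOn}/k_{metOff}$), driving RAS and PI3K
  independently of EGFR. A MET inhibitor binds both forms into inert
  complexes.

RAS, ERK, PI3K and AKT are conserved moieties whose totals are expression
parameters. Ligand, cetuximab and inhibitor are constant inputs (doses far
exceed receptor numbers on this timescale, so depletion is neglected); doses
are converted to nominal nM-equivalents using 6.2 kDa for EGF and 152 kDa
for cetuximab. AREG uses the identical network with the association constant
divided by a configurable affinity ratio (default 50).

Cell lines and media share one base parameterization; differences are
log-fold-changes, $\theta_{i,\mathrm{Hs746T}} =
e^{\xi_i}\,\theta_{i,\mathrm{MKN1}}$. Fold-changes are fixed to zero for
direct biochemical interactions (binding, dimerization), free for lumped
multi-step rates and expression levels, and between media only expression
levels may differ. The initial condition of every experiment is the
unperturbed steady state of the variant at its resolved parameters.

## Observation model and likelihood

Immunoblot observables are linear read-outs: total EGFR (counting dimers
twice), pEGFR, pERK, pAKT and — in the Hs746T variant — total MET and pMMET.
Each (observable, gel) pair has a multiplicative scaling factor mapping model
concentrations to densitometry units; replicates on one gel share the
scaling, different gels never do. Measurement noise is additive Gaussian
with an SD per (observable, gel), estimated once as the pooled
within-replicate SD (square root of the mean within-group variance, with a
floor of $10^{-3}$ times the observable range) and then held fixed. The
objective is the negative log-likelihood

$$-\log L = \tfrac12 \sum_i \left(\frac{y_i - h_i(\theta)}{\sigma_i}\right)^2
  + \tfrac12 \sum_i \log(2\pi\sigma_i^2),$$

with the constant written out so AIC values remain comparable across noise
maps. Mixture-model-based adaptation of replicate scales is out of scope
here; the two-stage pooled-SD scheme above is a simplified stand-in and is
labeled as such.

## Estimation

Positive parameters are optimized in log10, fold-changes on their natural
(additive) scale, within bounds of $10^{\pm 2.5}$ around the default values
(the defaults play the role of literature midpoints for the synthetic
system). Starting points come from Latin hypercube sampling; each start is
refined by a trust-region least-squares method (`minpack.lm::nls.lm`) on the
weighted residual vector with analytic Jacobians from forward sensitivities.
The compiled right-hand side integrates states and sensitivity columns
together (lsoda with an analytic system Jacobian); steady-state
sensitivities are obtained exactly from the linearized system at the
pre-equilibrated state, with conserved-moiety totals pinned to their
parametric values.

Multi-start results are sorted into a waterfall; starts within 0.1
negative-log-likelihood units of the best are labeled the global plateau
(the margin is a package choice; a likelihood-ratio note additionally marks
fits within $\chi^2_{0.95,1}/2 \approx 1.92$ as statistically
indistinguishable from the best). Scaling factors can optionally be profiled
analytically (conditional linear least squares, with exact chain-rule
Jacobian corrections) instead of being estimated by the optimizer; the
optimum is identical, the search space much smaller, so the ensemble and
batch studies below enable it.

## Model selection and parameter screening

Cell-line specificity is explored over three candidate modules: (i) RAS-MAPK
rates, (ii) PI3K-AKT rates, (iii) EGFR turnover (internalization,
degradation, recycling). All $2^3 = 8$ subsets form the hypothesis ensemble
M1 (nothing specific) through M8 (everything specific); expression and
mutation differences are free in every model, direct parameters shared.
Models are ranked by $\mathrm{AIC} = 2k + 2(-\log L)$ on the identical joint
dataset, with a difference of 10 treated as substantial support loss; ties
break by parsimony, then label order. Separately,
`compare_parameters_anova()` screens each lumped parameter across the best
fits of the two individually fitted cell lines by one-way ANOVA at raw
p < 0.05 (a Benjamini-Hochberg column is reported for guidance only; direct
parameters are excluded as "not tested").

## Uncertainty and identifiability

The Fisher information matrix is the Gauss-Newton product $J^\top J$ of the
weighted-residual Jacobian at the optimum, restricted to dynamical
parameters (scalings shape no dynamics). A spectrum whose extreme
eigenvalues differ by more than six orders of magnitude (strictly) is called
sloppy; eigenvalues below $\lambda_{max}\times 10^{-12}$ are reported as
numerical zeros. Profile likelihoods walk each parameter outward with
adaptive steps (targeting a 0.1 objective increase per step, steps clamped
to $[10^{-3}, 0.5]$ in scaled units), re-optimizing all remaining free
parameters, until the 99% threshold or a bound; confidence intervals
interpolate the $\chi^2_{\alpha,1}/2$ crossings, and a parameter whose 90%
interval is unbounded within the bounds is practically non-identifiable.

A structural note specific to this realization: the MET activation /
deactivation pair enters every observable only through its ratio. The
MMET–pMMET cycle is autonomous and linear, experiments start at its own
equilibrium, and the inhibitor binds both forms at the same rate (a shift of
the system matrix by a multiple of the identity, which preserves
eigenvectors). Individual values of $k_{metOn}$ and $k_{metOff}$ are
therefore not identifiable from any design expressible here — only their
ratio is. The identifiability study consequently fixes $k_{metOff}$ and asks
whether $k_{metOn}$, $k_{rasM}$ and $k_{pi3kM}$ become identifiable when
pMMET is measured: without pMMET data they trade off freely along a ridge
(practically non-identifiable); adding calibrated pMMET measurements pins
the pMMET level and resolves all three. This mirrors, at the level of the
synthetic system, the observation that MET-pathway parameters stay
unresolved until MMET activity itself is measured.

## The synthetic-data generator

`pathway_design()` emulates the study layout: EGF time courses
(0–240 min, default grid 0, 5, 15, 30, 60, 120, 240), cetuximab dose
responses (0.05–50 µg/ml at fixed EGF), EGF dose responses (5/30/100 ng/ml),
optional MET-inhibitor time courses, for each cell line and medium, with 3
replicates by default. Each (cell line, medium, series) is one gel with its
own scaling factor per observable, drawn log-normally (sdlog 0.2) around 1 —
reproducing, at configurable scale, the proliferation of observation
parameters that real blot data force. Noise SDs default to 10% of each
observable's scaled dynamic range, a signal-to-noise level at which
recovery is feasible but not trivial. The default truth uses the package
defaults as base values, the 2.5-fold EGFR expression difference, a medium
fold-change on receptor synthesis, and turnover-only module specificity with
$|\xi| = \ln 3$ — so the selected model of the synthetic system is M5 by
construction, and selection studies test whether the pipeline finds it.
Hs746T truth parameters make EGF responses weak because MET drive dominates
basal signaling; the non-responder phenotype emerges from mechanism rather
than from hard-coding.

What the generator does **not** emulate: densitometry nonlinearities and
saturation, image-processing artifacts, outliers, non-Gaussian noise, and
replicate-scale mixture structure. Passing recovery tests therefore
demonstrate the correctness and calibration of the estimation machinery on
data matching its assumptions, not robustness to real-blot pathologies.

## Numerical choices

* Integration: lsoda, relative tolerance $10^{-8}$, absolute $10^{-10}$
  (fits and the FIM need smooth objectives); batch studies (ensemble runs,
  repeated-seed recovery) relax to $10^{-7}/10^{-9}$, which leaves analytic
  and finite-difference Jacobians in agreement well below the testing
  tolerance.
* Pre-equilibration: simulate the unstimulated system to $t = 10^6$ min,
  then one damped pseudo-inverse Newton step; accepted when
  $\|\dot x\|_\infty < 10^{-8}$.
* Optimizer: `nls.lm` with a 300-iteration default cap and step tolerance
  $10^{-10}$; batch studies cap iterations harder (their purpose is
  best-of-many, not per-start polish).
* Dose unit conversion constants and the AREG affinity ratio are package
  constants documented above; rate constants absorb residual unit ambiguity.
* Tie-breaks in model ranking: parsimony first, then enumeration order.

## Problem sizes used by the shipped studies

The test suite and the acceptance script run the whole pipeline at desk
scale, chosen so a complete run stays within tens of minutes on one CPU:
parameter recovery uses a 144-point single-cell-line design (time course
plus cetuximab dose response, 3 replicates), 50 Latin hypercube starts, and
profiles over three representative kinetic parameters, across 10 seeds;
selection recovery uses a 64-point joint design (time courses, 2
replicates) with 20 starts for each of the 8 models across 10 replicate
datasets; the identifiability study uses Hs746T time courses plus one
inhibitor series. These sizes are the package's scaled-down rendition of the
study design (hundreds of points per cell line, 100–1000 starts), and all
of them are configurable.

## Known limitations

* The reaction set is a faithful minimal realization of the pathway
  cartoon, not a bit-identical reconstruction of any particular published
  equation set; lumped steps (dimerization/autophosphorylation, RAF/MEK)
  absorb intermediate kinetics.
* Internalized and membrane phospho-receptor signal with equal weight; the
  alternative (distinct weights) is one fold-change away but not a default.
* $k_{metOn}$/$k_{metOff}$ ratio-only identifiability, discussed above.
* Scaling-factor gauge freedom couples expression-level parameters with
  observation parameters; absolute abundances are only determined up to the
  calibration the data provide.
* The workflow targets one well-mixed compartment and deterministic
  kinetics; no spatial effects, no stochasticity, no ADCC, no
  proliferation endpoints.
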