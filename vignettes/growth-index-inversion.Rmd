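---
title: "Composite growth-index construction and spectral inversion: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composite growth-index construction and spectral inversion: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgmi)
```

## The problem

Stand-level growth of a woody crop is usually monitored through single
indicators — a chlorophyll-meter reading (SPAD), plant height (PH, m), leaf
area index (LAI) and aboveground biomass (AGB) — each of which captures one
facet of vigor. This package implements an integrated workflow: the four
indicators are fused into a single comprehensive growth monitoring index
(CGMI) per plot, the CGMI is related to vegetation indices computed from
five-band UAV multispectral reflectance (450, 550, 660, 750, 840 nm), and a
suite of regressors inverts the CGMI from the spectra, so that a flight can
substitute for field measurement.

## The composite index

Each indicator column $x_i$ is min–max normalized,
$U_i = (x_i - \min x_i)/(\max x_i - \min x_i)$, so the best-growing plot
scores 1 and the worst 0 on every axis. Two weightings are provided:

* **CGMI$_1$** $= \tfrac14 \sum_i U_i$ (equal weights);
* **CGMI$_2$** $= \sum_i W_i U_i$ with $W_i = V_i / \sum_j V_j$, where
  $V_i = S_i/\bar x_i$ is the coefficient of variation of the **raw**
  indicator column.

The CV weighting rewards indicators that discriminate between plots. Two
choices here were genuinely open and are worth recording:

* **CVs on raw columns, not normalized ones.** Normalizing first would make
  every column's mean depend on the arbitrary position of its minimum,
  grossly distorting relative dispersion; computed on raw columns the weights
  are invariant to the units of each indicator (a property the test suite
  asserts), and renormalizing the published dispersion profile of this kind
  of campaign (CVs 0.09, 0.17, 0.22, 0.23) reproduces the published weights
  to within rounding.
* **Population vs sample SD.** Published summary tables at two decimals
  cannot discriminate $n$ from $n-1$; the population convention is the
  default and `sample = TRUE` switches.

Normalization bounds are taken from the full campaign, not the training
split — the composite index is a property of the campaign, defined before
any modelling. This is a deliberate, documented leakage of the target's
scaling (not of the model's inputs).

## The vegetation-index library

Twelve broad-band indices are registered (NDVI, GNDVI, MSR, TCARI,
CIrededge, DVI, OSAVI, VDVI, SIPI, MTVI, MNVI, ARVI). Source tables for
index formulas are notoriously prone to typographic damage; each registry
entry therefore carries a provenance flag, `as-printed` or
`literature-corrected`, retrievable with `index_registry()`. Four entries
(MSR, CIrededge, MNVI, MTVI) are evaluated in their canonical literature
forms by default because the printed strings are transcription artifacts
(e.g. `NIR/(RE−1)` for a red-edge chlorophyll index). Where an artifactual
string still parses, `formulas = "as-printed"` evaluates it literally for
auditability. Division by zero raises an error naming the plot; it never
produces a silent `NaN`.

## The synthetic campaign generator

Real campaigns of this kind are small (66 plots here) and unpublished, so
the package carries a generator that reproduces the *statistical structure*
the analysis depends on, making every downstream stage testable:

* one latent **vigor** scalar per plot, standard normal;
* each indicator is `loading × vigor + noise`, standardized and affinely
  mapped onto the campaign marginals (SPAD 40.18 ± 3.75, PH 1.18 ± 0.20 m,
  LAI 2.90 ± 0.63, AGB 6348 ± 1516). Loadings default to
  (0.88, 0.72, 0.85, 0.85) — plant height is the weakest because height
  carries the least spectral signal;
* each band is `baseline + slope × vigor + noise`, clamped to (0.01, 0.99),
  with NIR rising and red falling in vigor. The red baseline (0.15) is
  relatively high, as for a young sparse canopy over reddish soil, and NIR
  carries the largest noise (canopy-structure variation). These values were
  fixed once so that the chlorophyll-sensitive TCARI correlates with
  CGMI$_2$ at the strength a real campaign shows (r ≈ 0.6–0.9) and leads
  the index ranking; they are defaults of the study conditions, not tuning
  knobs.

What the generator does **not** emulate: spatial autocorrelation between
plots, multi-date phenology, sensor miscalibration, and any nonlinearity in
the indicator–reflectance link. A model that passes on synthetic data has
been shown correct *mechanically*, not validated against field truth.

## Screening

Every index is correlated (Pearson, two-sided t test) with the four
indicators and both composite indices. Inputs to the models are the five
indices with largest |r| against CGMI$_2$ among those significant at
α = 0.01. The reference protocol instead fixes the five named indices
(TCARI, CIrededge, OSAVI, DVI, MNVI); both modes are available because the
original index set reflects manual redundancy judgement no algorithm was
given for. The pairwise index–index correlation matrix is reported so users
can audit redundancy themselves.

## The regressors

Reference hyperparameters: MLR (OLS); PLS with 2 NIPALS components; SVR
(ε-insensitive, RBF kernel, penalty 20, kernel parameter 30 read as the
kernel-scale σ, i.e. γ = 1/σ²; ε = 0.01 on the [0,1] target); RF (100
trees, minimum node size 4, seeded); RBFNN (Gaussian basis with spread 100,
centers added greedily at the worst-fit training point up to
min(n, 25), linear output solved by least squares); and a 5–12–1 tanh
back-propagation network.

The BPNN is trained by full-batch Levenberg–Marquardt with the analytic
Jacobian (maximum 1000 iterations, goal MSE 10⁻⁴, random start uniform in
[−1, 1]). A learning-rate/batch-size gradient-descent fallback
(`algorithm = "gd"`, lr 0.1, batch 9) is kept because the reference
protocol lists those knobs, but L–M — the trainer the protocol names — is
full-batch and is the default.

**Early stopping.** The 85-parameter network can interpolate 52 noisy
training plots, at which point test accuracy collapses. Classic NN
toolchains guard against this by holding out a validation slice; the
trainer follows that convention (`val_fraction = 0.15`, patience
`max_fail = 6`, best-validation parameters returned; `val_fraction = 0`
disables). The returned parameters never score worse on the full training
set than the supplied start, which keeps refinement consistent with the
whale-search optimum below.

## The whale optimization algorithm

The WOA is a population metaheuristic mimicking humpback bubble-net
hunting. Each agent, each iteration, either *encircles* a leader —
$x' = x^\star - A \cdot |C x^\star - x|$ with $A = 2ar - a$, $C = 2r$,
$r \sim U(0,1)$ drawn per dimension, the leader being the best agent while
$|A| < 1$ and a random agent otherwise — or follows a logarithmic *spiral*
around the best, $x' = x^\star + |x^\star - x|\, e^{bl} \cos 2\pi l$,
$l \sim U(-1,1)$, the branch chosen with probability ½. The shrink
coefficient $a$ falls linearly from 2 to 0 over $T$ iterations, so late
iterations are purely exploitative. Positions are clamped to the search
box; the best agent is updated greedily, so the best-fitness trace is
monotone non-increasing (asserted on every run). Draws are per dimension —
the original formulation's convention, and the one that reproduces the
published benchmark behavior (10-D sphere to ~10⁻⁵⁰ at population 30, 500
iterations; a per-agent-scalar variant stalls around 10⁻³).

**WOA → BPNN wiring.** The search space is the flat 85-vector of network
weights and thresholds in [−1, 1] per dimension (tanh's active range; the
bounds are configurable). Fitness is the raw network's MSE on the training
rows — no inner training during the search — and the search optimum then
replaces the random start of the L–M trainer. The fitness is computed only
on the rows the trainer will actually fit: scoring the validation hold-out
would let the search pre-fit the early-stopping monitor and quietly defeat
it. Reference protocol: population 10, 60 iterations (600 forward passes).

## Accuracy metrics and protocol

The campaign's 66 plots split 52/14 (seeded uniform partition). Reported
per model and set: the ratio R² $= \sum(\hat a_i - \bar b)^2 / \sum(a_i -
\bar b)^2$ exactly as the reference prints it (it can exceed 1; the worked
example (1,2,3)/(1,2,4) gives 2.5), the conventional $1 - SSE/SST$
alongside, RMSE, NRMSE normalized by the **predicted** range as printed
(observed-range option available), and MAPE in percent. Model comparisons
in the tests use the conventional R², which is bounded and standard.

## Numerical choices and degenerate inputs

Constant indicator columns (zero range), zero means, constant correlation
inputs, zero denominators in indices, non-finite objective values at the
initial whale population, and singular MLR designs all raise immediate,
named errors rather than propagating `NaN`. All randomness flows through
explicit seed arguments (generator, splits, RF bootstrap, network starts,
WOA); the pipeline expands one master seed per stage by stable name
hashing, so stage-level reruns reproduce in isolation. Problem sizes used
in the shipped analyses — 66 plots, 20 paired replicate campaigns for the
WOA-vs-random comparison, 10 sphere-benchmark seeds — are the campaign
scale of the protocol itself.

## Known limitations

* Synthetic validation only: the package demonstrates mechanism, not field
  accuracy; published real-data headline numbers (e.g. test R² ≈ 0.90 for
  the whale-initialised network) require the original measurements.
* The WOA advantage over a well-regularized random-start network is modest
  at this problem size — a median improvement over paired campaigns, not a
  guarantee per campaign.
* The ratio-form R² is reported for fidelity but is not a goodness-of-fit
  measure for biased predictors; read it next to the conventional R².
* The single 52/14 split follows the reference protocol; no outer
  cross-validation is performed.
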