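---
title: "Source-to-outcome mixture risk modelling with toxrisk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Source-to-outcome mixture risk modelling with toxrisk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7,
  fig.height = 4.5)
library(toxrisk)
library(dplyr)
```

## The modelling problem

Regional air-monitoring and dispersion models supply, for each region
(a county, a census tract, or an individual address), the mean and
standard deviation of the outdoor air concentration of many hazardous
chemicals. High-throughput in-vitro screening supplies, for each
chemical and assay endpoint, a concentration–response curve measured in
µM. These two worlds meet only after a chain of conversions: a person
inhales air at a rate that depends on their age; the inhaled mass
becomes an internal dose per kg body weight; steady-state toxicokinetic
scaling converts that dose rate into the plasma concentration it would
sustain, which is the quantity comparable to the in-vitro assay medium.
Once every chemical's exposure is expressed in assay units, mixture
dose–response theory combines the per-chemical curves into a joint
predicted effect, and a hazard quotient locates that effect relative to
a reference response level. `toxrisk` implements this chain end to end,
with Monte Carlo population simulation supplying the between-individual
variability at every step.

The package deliberately starts *after* geospatial exposure assessment:
the exposure table (mean/sd per region × chemical) is an input, not
something the package estimates. Likewise the steady-state plasma
concentration (Css) samples arrive as a pre-simulated table — they are
typically produced upstream by a physiologically based toxicokinetic
model at a tractable sample size and are bootstrap-resampled here.

## The model, step by step

**Hill concentration–response.** Each chemical × assay curve is the
log-logistic hill function in log10 concentration,

$$f(c) = \frac{tp}{1 + 10^{(\log_{10}AC_{50} - \log_{10} c)\,\cdot\, slope}},$$

with top $tp$ (% activity), half-maximal concentration $AC_{50}$ (µM)
and hill coefficient $slope$. `fit_hill()` obtains the maximum
likelihood estimate under independent Gaussian residuals with a free
scale $\sigma$. The residual scale is profiled out analytically
($\hat\sigma^2 = SS/n$ at any mean-parameter value), which reduces the
problem to bounded nonlinear least squares; we solve it by
Levenberg–Marquardt, a choice made for numerical conditioning — the
optimum is the same MLE a quasi-Newton search of the full likelihood
would find, but convergence is far more reliable on sigmoid curves.
Standard errors come from the inverse observed information of the full
likelihood (including the $\log\sigma$ row). A fit is declared
converged only when the optimizer reports success, the gradient norm of
the negative log-likelihood is below $10^{-6}$ (relative to its
magnitude), the observed information is positive definite, and the
solution is interior to the box ($tp \in (0, 1.5\cdot\max resp]$,
$slope \in [0.3, 8]$). Boundary or degenerate solutions (for instance a
response vector that is all zeros) are flagged, not fitted, and flagged
curves never enter the analysis roster.

The default is the 2-parameter variant with $slope = 1$. That is not
merely a simplification: the closed-form generalized concentration
addition solution below is only available at unit slope, and unit-slope
fits keep the mixture algebra exact.

**The chemical roster.** `assemble_model()` intersects three chemical
sets: chemicals with exposure records, chemicals with at least one
converged curve fit, and chemicals with Css samples. Only the
intersection is analyzed; everything dropped is retained in the model's
provenance with the reason. Assays may cover different subsets of the
roster (screening libraries rarely align perfectly); the roster is
global and each assay is evaluated on the roster chemicals it covers.
Whether per-assay coverage should instead shrink the global roster is
genuinely ambiguous in practice; we chose the global roster because it
preserves every usable curve, and per-assay subsets fall out of it
naturally.

**Population simulation.** For each region, `simulate_population()`
draws `n_per_region` individuals:

* *age* — a census-style bracket is chosen multinomially by its
  population share, then an integer age uniformly inside the bracket
  (the open-ended top bracket is encoded as 85–99);
* *obesity* — one region-level prevalence is drawn from
  Normal(mean, sd) truncated to [0, 1], then each individual is an
  independent Bernoulli at that prevalence. The two-stage scheme
  propagates the survey uncertainty of the prevalence estimate rather
  than treating it as exact;
* *inhalation rate* — Normal(mean, sd) of the age-matched bracket,
  truncated at 0, in m³ per kg body weight per day;
* *external exposure* — per chemical, Normal(mean, sd) truncated at 0.
  The truncated normal is our choice of family: exposure products
  publish means and standard deviations without naming a distribution,
  and truncation at zero is the minimal physically motivated
  correction;
* *Css* — one bootstrap draw per individual × chemical from the
  pre-simulated sample vector of the individual's (age group, weight
  class) stratum. Age groups default to 0–17, 18–44, 45–64, 65+.

All randomness flows through deterministic substreams keyed by
(master seed, region, component). Two consequences matter: regions can
be simulated in any order with identical results, and the sensitivity
analysis can re-draw exactly one component while reproducing every
other component's draws bit for bit.

**Calculators.** With inhalation rate already per kg body weight, the
internal dose is the product
$D = C_{ext} \cdot IR \cdot t \cdot s$ with exposure time $t$ defaulting
to 1 day (the Css scaling assumes steady state within a day) and unit
scaling $s = 10^{-3}$ (µg → mg). The in-vitro-equivalent concentration
is simply $D \cdot C_{ss}$ (µM).

**Mixture response.** Two combination rules are implemented:

* *Generalized concentration addition (GCA)* solves
  $\sum_i C_i / f_i^{-1}(E) = 1$ for the joint effect $E$. At unit
  slope the inverse is $f^{-1}(E) = AC_{50} E/(tp - E)$, which remains
  meaningful beyond a partial agonist's own top (the signed inverse),
  and the solution is closed-form:
  $E = \sum_i C_i\,tp_i/AC_{50,i} \big/ (1 + \sum_i C_i/AC_{50,i})$.
  With non-unit slopes the inverse is only defined below each top, so
  the root is bracketed on $(0, \min_i tp_i)$; when no root exists
  there the boundary value is returned with a flag. The closed form is
  the default path and the root-finder is held to it by tests.
* *Independent action (IA)* multiplies survival fractions of effects
  normalized by a reference maximum $E_{ref}$:
  $E = E_{ref}(1 - \prod_i (1 - f_i(C_i)/E_{ref}))$. We take
  $E_{ref} = \max_i tp_i$ over the assay's covered chemicals, the
  smallest reference that keeps every factor in [0, 1].

**Hazard quotient.** The HQ compares the mixture's concentration
vector to the concentration, *at the same component ratio*, that
produces a reference response — here `hq_percent`% (default 10) of
$E_{ref}$. We find the scalar $s^*$ with
$\text{response}(s^* \cdot \mathbf{C}) = 0.1\,E_{ref}$ by monotone
root bracketing on $\log_{10} s \in [-12, 12]$ (absolute tolerance
$10^{-10}$) and report $HQ = 1/s^*$. This whole-mixture inversion is
exactly homogeneous of degree 1 in the concentrations. The additive
hazard-index convention $\sum_i C_i/EC_{p,i}$ is available as a named
option (`convention = "hazard_index"`) but is not the default, because
it ignores mixture interaction under the response model and is
undefined for components whose top lies below the reference response.
If the reference response is unreachable at any scaling (a mixture
dominated by weak partial agonists), the HQ is 0 with a flag rather
than an error.

**Nested quantile summaries.** Multi-assay risk is summarized per
region as the *p*-th total quantile across assays of the *q*-th
assay-level quantile across individuals. All percentiles are empirical
with linear interpolation between order statistics (`type = 7`); the
estimator choice is ours and is applied uniformly, so the grid is
always monotone in *q*. Assay-level quantiles are taken over
individuals *within* region; summarizing over regions instead would
answer a different (state-level) question and is not what the
choropleth maps need.

**Sensitivity.** `compute_sensitivity()` varies one component — age,
obesity, Css, curve-fit parameters, or external concentration — while
pinning the rest to central values: region median age (computed
analytically from the bracket distribution), weight class Normal,
age-bracket mean inhalation rate, exposure mean, stratum-median Css,
and maximum-likelihood curve parameters. When the fit parameters vary,
they are drawn per replicate from independent normals centred at the
MLE with the fitted standard errors, truncated to valid ranges
(covariances between curve parameters are not propagated; with them
the draws would be slightly tighter, so the independent-normal choice
is conservative). Because every component owns its RNG substream,
pinning a component reproduces the baseline exactly, and the baseline
run with everything pinned has exactly zero variance within each
region × assay.

## The synthetic study

`gen_synthetic_study()` produces a complete input bundle with known
ground truth: a grid of unit-square regions; exposure means drawn
log-normally (median 5 µg/m³, geometric sd ≈ 1.65) with sd fixed at
30% of the mean, mimicking the signal-to-noise of modelled annual
air-toxics surfaces; true hill curves with $tp \in [50, 120]$,
$\log_{10} AC_{50} \in [-1, 1]$ and unit slope; responses observed at
log-spaced concentrations ±2.5 decades around the true AC50, three
replicates, Gaussian noise (default sd 3% activity); Css strata of 50
log-normal samples per chemical × age group × weight class with the
obese strata shifted ×1.2 (an arbitrary, documented effect size that
makes weight-class contrasts visible, not a physiological claim);
census-like age brackets; and an inhalation-rate table decreasing with
age, in the range of reference long-term inhalation rates per kg. When
two or more assays are requested, each assay after the first is
missing one chemical, so per-assay coverage genuinely differs from the
global roster.

What the generator does *not* emulate: spatial autocorrelation of
exposure, realistic curve pathologies (cytotoxicity bursts, gain–loss
shapes), hit-call uncertainty, or correlated toxicokinetics across
chemicals. Green tests on this study demonstrate that the machinery is
correct under its stated assumptions, not that those assumptions hold
for any particular real dataset.

## A complete run

```{r pipeline}
study <- gen_synthetic_study(n_regions = 5, n_chems = 4, n_assays = 2,
  seed = 42)
model <- assemble_synthetic(study, risk_config(seed = 42, n_per_region = 200)) |>
  simulate_population() |>
  calc_response() |>
  summarize_risk("GCA_HQ")
model
```

```{r results}
model$results |> head()
region_summary(model, "GCA_Eff", quantiles = 50) |> head()
model$summary |> head()
```

```{r figures, eval = FALSE}
autoplot(model, type = "hill")
autoplot(model, type = "response")
model <- run_sensitivity(model, metric = "GCA_Eff")
autoplot(model, type = "sensitivity")
```

The same analysis runs from a YAML configuration with
`run_pipeline("config.yaml")`; `write_study()` emits a ready-made
bundle including the configuration, and repeated runs with the same
seed write byte-identical output trees.

## Numerical choices and degenerate inputs

* Root-finding tolerances: GCA general-slope root to
  $10^{-13}\cdot\min tp$ absolute; HQ scaling root to $10^{-10}$ on
  $\log_{10} s$; both well inside the $10^{-8}$ agreement the tests
  demand.
* The slope-1 GCA row computation uses explicit row-wise sums
  rather than BLAS matrix multiplication so that identical individuals
  yield bit-identical effects (vectorized BLAS may round remainder
  rows differently — invisible numerically, fatal for exact
  zero-variance baselines).
* Truncated normal draws use inverse-CDF sampling, which is exact for
  sd = 0 and never loops.
* All-zero concentration vectors short-circuit to effect 0 and HQ 0.
* Age brackets with `age_low == age_high` are valid (point masses);
  bracket proportions must sum to 1 within $10^{-9}$.
* A concentration–response group needs at least five distinct
  concentrations; fewer is an error rather than a silent bad fit.

## Problem sizes

The bundled end-to-end study uses 5 regions × 4 chemicals × 2 assays
with 200 individuals per region; fit-recovery studies use 500 curves
of 10 concentrations × 3 replicates. These sizes give stable Monte
Carlo summaries (binomial error on a median over 200 individuals is
well under the effects being checked) while keeping a full test cycle
under a minute on a single core. Larger studies scale linearly in
regions × individuals; the calculators are vectorized over individuals
on the closed-form path.

## Known limitations

* Inhalation is the only exposure route; no dermal or oral intake.
* The hill family is the only dose–response model; no gain–loss or
  polynomial alternatives, no model averaging, and no hit-call
  derivation (hit-call filtering is assumed upstream).
* Gaussian residuals in the curve fit are an explicit, swappable
  assumption; heavy-tailed screening noise will inflate the flagged
  non-convergence rate before it corrupts estimates.
* The one-at-a-time sensitivity design quantifies each component's
  marginal contribution; it is not a variance decomposition and does
  not capture interactions between components.
* Geometry handling is intentionally minimal (WGS84 polygons/points,
  web-mercator ingestion); the package is not a geospatial analysis
  tool.
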