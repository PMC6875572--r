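---
title: "Methods: isotopic niche, diet mixing and trait-change partitioning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: isotopic niche, diet mixing and trait-change partitioning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isonich)
```

`isonich` analyses consumer stable-isotope time series from lakes and
reservoirs. Its workflow follows the standard design of zooplankton
trophic-ecology studies: consumer δ¹³C/δ¹⁵N replicates per taxon group and
date, food-source isotope summaries (here, pico-/nano-/micro-POM size
fractions by water layer), taxon abundance and body-size series, and an
environmental series over a mixing (cold, fully mixed water column) and a
stratification (warm, layered) period. This vignette documents the models,
their assumptions, the tunable parameters, and the design decisions taken
where the methodology is genuinely open.

## Preprocessing

**Lipid correction.** Lipids are ¹³C-depleted, so lipid-rich tissue biases
δ¹³C low. The correction is a configurable linear model in the C:N ratio,
`d13C + intercept + slope × C:N`, and is off by default: published
normalisation coefficients differ among calibration studies and taxa, so we
require the analyst to supply them explicitly rather than bake in any one
calibration. δ¹⁵N is never touched by this step.

**Baseline standardization.** Euclidean niche metrics are comparable across
dates only if the resource baseline is removed. A source anchors the
baseline if its posterior mean diet contribution exceeds 12% (strict `>`)
in at least one period; consumer values are then transformed per axis as
`(x − baseline mean) / baseline range`. Because "mean and range of the
retained sources" can be pooled in more than one way, both a pooled-means
mode (default) and an SD-envelope mode are exposed; the transformation is
affine either way, so correlation structure, and hence ellipse shape, is
preserved exactly. Both axes use the same retained source set by default;
per-axis sets can be obtained by calling `baseline_spec()` per axis.

**Derived environmental variables.** Dissolved CO₂ is speciated from DIC,
temperature and pH with the freshwater carbonic-acid dissociation constants
of Plummer & Busenberg (1982) (pK₁ = 6.352, pK₂ = 10.329 at 25 °C); DIC is
interpreted as mg C/L and reported in µmol/L. Euphotic depth is 2.7 ×
Secchi depth. CO₂(aq) is monotone decreasing in pH at fixed DIC and
temperature — a property the test suite checks.

## Niche metrics

`layman_metrics()` computes the six community-wide descriptors of a
δ¹³C–δ¹⁵N point set: CR and NR (axis ranges: basal-resource
diversification and trophic length), CD (mean distance to centroid:
trophic diversity), MNND and SDNND (nearest-neighbour packing density and
evenness; low MNND = high trophic redundancy) and TA (convex hull area).
SDNND uses the sample (n−1) standard deviation by convention; a population
mode is available. Hulls of fewer than three distinct non-collinear points
are flagged degenerate with `TA = NA` rather than zero, so downstream
tables can distinguish "no area" from "not estimable".

The standard ellipse area is `SEA = π√det(S)` for the sample covariance
`S`, i.e. the 1-SD ellipse (~40% of the mass) — the conventional scale for
isotopic niche breadth; a p-level ellipse is available in
`ellipse_overlap()` via `scale = qchisq(p, 2)`. The small-sample correction
is `SEA_C = SEA·(n−1)/(n−2)`.

**Bayesian SEA (`sea_b`).** The data are modelled as bivariate normal with
the Jeffreys reference prior `p(µ, Σ) ∝ |Σ|^{-3/2}`. The posterior of `Σ`
is then inverse-Wishart with `n − 1` degrees of freedom and the centred
sum-of-squares as scale, which we sample by direct Monte Carlo — every
retained draw is independent, so no convergence diagnostics are needed;
the configured burn-in and thinning are still applied to the raw draw
stream so run lengths line up with MCMC-based tools. Each draw yields
`π√det(Σ)`. The point estimate is the histogram-peak mode
(Freedman–Diaconis bins; kernel-free, so no bandwidth choice), with the
median reported alongside because the mode of a finite draw set is the
noisier statistic. Central 50/75/95% credible intervals are reported.

**Ellipse overlap** integrates the intersection indicator on a regular
grid over the intersection of the two ellipse bounding boxes (default
401 × 401); the proportion is Jaccard-style,
`overlap / (area_a + area_b − overlap)`. Grid integration was chosen over
Monte Carlo for determinism; the tests verify agreement with an
independent Monte Carlo hit count.

## Diet-source mixing

**Mixing-polygon screening.** Before any mixing fit, consumers the sources
cannot plausibly explain are flagged: per iteration, each
enrichment-corrected source vertex is drawn from
`N(µ_s + f, √(σ_s² + τ²))` per axis, the convex hull is formed, and each
consumer is tested point-in-hull. Boundary points count as inside —
tie-breaking is unstated in the screening literature and the inclusive rule
is conservative against exclusion. A consumer is excluded when its
inclusion probability falls below 0.05, the complement of the 95%
simulated mixing region.

**Mixing model.** Consumers within one fitted unit (community × period)
share a single diet-proportion vector `p` with a flat Dirichlet(1) prior;
per isotope `k`,

`x_jk ~ N( Σ_s p_s (µ_sk + f_k),  Σ_s p_s² (σ_sk² + τ_k²) + ε_k² )`

with trophic-enrichment means `f = (0.4, 3.4)` ‰ and SDs
`τ = (1.3, 1.0)` ‰ by default — the standard consumer literature values —
and residual SDs `ε_k` with weakly-informative half-normal(0, 5) priors
(disable `resid_err` to get the exact process model for oracle tests).
Sampling is random-walk Metropolis on centred-log-ratio coordinates plus
`log ε`, with the Dirichlet prior entering through the softmax Jacobian.
Step sizes adapt toward ~30% acceptance during burn-in only, so the
retained chain is a valid fixed-kernel sample. Four chains run by default;
split-R̂ and a crude autocorrelation-based effective sample size are
reported per source, with a non-convergence warning at R̂ > 1.1. Default
run length is 20,000 iterations, 2,000 burn-in, thinning 20.

Two isotopes support only two identifiable mixture dimensions, so with
more than three (or collinear) sources the per-source posterior shrinks
toward the prior mean — the familiar limitation of isotope mixing models.
The package reports full posteriors so the analyst can aggregate sources
(e.g. a pooled pico-POM fraction) where individual ones are weakly
identified.

## Price-equation partitioning

The change in a community-aggregated trait between two snapshots,
`Δz̄ = Σ q′z′ − Σ qz`, is decomposed into taxa sorting (TS), intrataxonomic
variation (ITV) and taxa turnover (TT). A naive pairing that multiplies
`z′` by `Δq` *and* `q′` by `Δz` over shared taxa double-counts the
abundance–trait covariation and does not sum to `Δz̄`; exact additivity is
non-negotiable here (it is enforced to 1e-12 in the tests), so the default
is the telescoping pairing

* `TS = Σ_shared z_i (q′_i − q_i)`
* `ITV = Σ_shared q′_i (z′_i − z_i)`
* `TT = Σ_gained q′z′ − Σ_lost qz`,

which telescopes exactly to `Δz̄`. A three-term mode reports
`TS = Σ z Δq`, `ITV = Σ q Δz` and the covariation `COV = Σ Δq Δz`
separately (also exactly additive) for analysts who prefer the symmetric
decomposition; both modes can be reported side by side.

Relative contributions are `|X| / Σ|components| × 100` — components of
opposite sign both register positive shares, and percentages sum to 100.
An optional rarity threshold routes taxa below a given relative abundance
(e.g. 3%) into the turnover term. `aggregate_snapshots()` builds
period-level snapshots (mean relative abundance, renormalised, and mean
trait per taxon) so change can be partitioned between whole periods as
well as between consecutive dates; `link_contributions_env()` Spearman-
correlates component contributions with environmental deltas over the same
consecutive pairs, with listwise deletion and per-cell flags for
insufficient (< 4 pairs) or constant data.

## Environment statistics and path modeling

PERMANOVA on the Euclidean distance of the z-scored variable matrix is
delegated to `vegan::adonis2()`; the module reports both a grouped run and
marginal per-variable runs (the per-variable design mirrors the common
table layout of one R² per variable against the same grouping). Variables
are typically log-transformed upstream (all but pH, which is already a
log) — the transformation is the analyst's, recorded in their workflow.

Collinearity pruning is greedy in column order: a variable is dropped when
|Spearman ρ| > 0.7 with p < 0.05 against an already-retained variable; the
order-dependence is deliberate and documented, as no principled ordering
is implied by the method. VIF filtering then iteratively removes the
largest `VIF_j = 1/(1 − R²_j) ≥ 10`.

The PLS path model uses reflective (mode-A) outer weights for all blocks —
matching the "loadings" interpretation — and the centroid inner scheme by
default (the classical default; factorial and path schemes are available,
and the tests check they agree on well-behaved data). Latent scores are
unit-variance; each latent is oriented so the sum of its loadings is
positive, making results deterministic. Path coefficients are OLS fits of
each endogenous latent on its predecessors; communality is the squared
loading, and `GoF = √(mean communality × mean R²)`. Indicators with
|loading| < 0.7 are pruned and the model refit. Bootstrap (percentile)
intervals and two-sided tail-mass p-values with significance at α = 0.10
are provided; the resample count defaults to 200 and is configurable.

## The synthetic reservoir generator

`synth_generate()` emulates the statistical structure the pipeline
assumes, not reservoir physics. Defaults encode the study design and
reported effect *directions*; magnitudes are field-typical choices fixed
once, since no raw field tables are available to calibrate against:

* 21 dates on a 20-day cadence from 1 Nov 2015; May–October is labelled
  stratification. Period mean temperatures 18.97/27.11 °C with a smooth
  seasonal component (±2 °C within period) plus 0.3 °C noise.
* Six taxon groups (Bosmina, Bosminopsis, other Cladocera, small and large
  Cyclopidae, Diaptomidae) with baseline dry weights 0.6–3.4 µg/ind and
  per-°C body-size slopes negative for all but small Cyclopidae (positive)
  and Diaptomidae (flat).
* Relative abundances are a softmax of temperature-dependent affinities
  whose signs favour small taxa when warm, so taxa sorting dominates the
  body-size change between periods; taxa below 2% relative abundance are
  treated as absent, generating occasional turnover.
* Six POM sources (three size fractions × two layers) with fixed
  signatures; the date-level diet blends log-linearly from a balanced
  mixed-period target to a surface-pico-dominated stratified target
  (73% pico-surface) as temperature rises.
* Within-group isotopic dispersion scales as `exp(−0.08 (T − T̄))`, so
  every group's ellipse — and the community ellipse — is wider in the
  mixing period and intrataxonomic variation dominates the niche-breadth
  change.
* Only temperature (strongly) and dissolved oxygen (weakly) separate the
  periods in the environmental series; the other variables fluctuate
  mostly independently, which keeps collinearity pruning non-trivial and
  mirrors the typical monomictic pattern.

The generator returns the full ground truth (noise-free trajectories,
per-date diet, abundances and traits), and `expected_partitions()` turns it
into an oracle for the partitioning pipeline: with all noise set to zero
the pipeline must reproduce it exactly, and at default noise the recovered
structure must match in distribution. What passing these tests does *not*
show: robustness to real-data features the generator omits — unbalanced
replication, missing dates, non-normal isotope noise, source signatures
drifting within a period, and taxonomic misassignment.

## Numerical choices and limitations

* Problem sizes in the tests (e.g. 50-seed generator sweeps, 2,000-iteration
  polygon simulations, 4,000-iteration reduced mixing fits, 200-repeat
  permutation-null sweeps) were chosen as the smallest sizes at which the
  checked contrasts are decisive.
* All stochastic functions are pure functions of (inputs, seed); chain `c`
  of the mixing sampler uses `seed + 1000(c−1)`.
* Degenerate inputs are first-class: singular covariances flag `SEA = 0`
  with a degeneracy marker, degenerate hulls yield `TA = NA` plus flag,
  all-zero partitions yield `NA` relative contributions plus flag, and
  constant indicators or variables raise named errors.
* The mixing sampler is a single community-level `p` per fitted unit; no
  per-individual random effects, concentration dependence or isotope
  routing.
* Ellipse overlap is numerical (grid) rather than closed-form; resolution
  is configurable, and accuracy ~0.5% at the default grid.
* Only two isotope axes are supported throughout; hull-volume metrics in
  higher dimensions are out of scope.
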