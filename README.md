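# isonich

Quantitative toolkit for stable-isotope trophic ecology of zooplankton
time series in lakes and reservoirs.

Field studies of this kind ask how warming restructures a plankton
community: consumer δ¹³C/δ¹⁵N replicates are collected per taxon group
across a year spanning a cold fully-mixed period and a warm stratified
period, together with food-source isotope summaries (POM size fractions by
water layer), taxon abundances and body sizes, and an environmental
series. `isonich` implements the full analysis chain those studies run:

* **Diet-source mixing** — a Bayesian mixing model with trophic-enrichment
  factors (defaults 0.4 ± 1.3 ‰ for δ¹³C, 3.4 ± 1.0 ‰ for δ¹⁵N),
  community-level diet proportions `p ~ Dirichlet(1)` sampled by
  random-walk Metropolis on log-ratio coordinates, and an a-priori Monte
  Carlo **mixing-polygon screen** that excludes consumers outside the 95%
  simulated mixing region.
* **Isotopic niche metrics** — Layman community-wide metrics (CR, NR, CD,
  MNND, SDNND, hull area), the standard ellipse area `SEA = π√det(S)`
  with small-sample correction `SEA_C`, a Bayesian posterior `SEA_B`
  (inverse-Wishart under the Jeffreys prior, mode + 50/75/95% credible
  intervals), ellipse overlap, and resource-baseline standardization.
* **Price-equation partitioning** — the change in a community-aggregated
  trait `Δz̄ = Σq′z′ − Σqz` split exactly into taxa sorting
  `TS = Σ z(q′−q)`, intrataxonomic variation `ITV = Σ q′(z′−z)` and
  turnover `TT`, with relative contributions and Spearman linkage of those
  contributions to environmental change.
* **Environment statistics** — one-factor PERMANOVA (via `vegan`),
  greedy Spearman collinearity pruning (|ρ| > 0.7, p < 0.05) and VIF < 10
  filtering.
* **PLS path modeling** — mode-A latent blocks, loading-based pruning at
  0.7, path coefficients, R², `GoF = √(mean communality × mean R²)`, and
  bootstrap significance at α = 0.10.
* **Synthetic reservoir generator** — a 21-date, two-period series (period
  mean temperatures 18.97/27.11 °C, six taxon groups, six POM sources)
  with full ground truth for recovery testing.

## Worked example

```r
library(isonich)

b <- synth_generate(synth_config(), seed = 42)

# community-weighted mean body size per period
cwm <- vapply(b$snapshots, community_weighted_mean, numeric(1))
per <- vapply(b$snapshots, function(s) s$period, character(1))
mean(cwm[per == "mixing"]); mean(cwm[per == "stratification"])
#> CWM dry weight (ug/ind): mixing 2.10 | stratification 1.28

# Bayesian niche breadth of the mixed-period community
mix <- b$consumers[b$consumers$period == "mixing", c("d13C", "d15N")]
post <- sea_b(mix, iso_config(seed = 1))
#> SEA_B mixing: mode 5.25  95% CI 4.61 - 6.02

# partition the between-period body-size change
agg_m <- aggregate_snapshots(b$snapshots[per == "mixing"], "mixing")
agg_s <- aggregate_snapshots(b$snapshots[per == "stratification"], "stratification")
price_partition(agg_m, agg_s)
#> Body-size change -0.811 ug/ind | TS 86.3% ITV 13.7% TT 0%

# which environmental variables separate the periods?
permanova_one_factor(log(as.matrix(b$env[, c("temperature", "DO", "chla")])),
                     b$env$period, n_perm = 999, seed = 1, per_variable = TRUE)
#>                r2      f     p
#> temperature 0.770 63.735 0.001
#> DO          0.521 20.634 0.001
#> chla        0.334  9.511 0.006
```

The community is smaller-bodied and trophically narrower when stratified;
the body-size shift is dominated by taxa sorting (abundance shifts toward
small taxa), while — as the per-taxon ellipses show when partitioned the
same way — the niche-breadth contraction is dominated by within-taxon
(intrataxonomic) variation.

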