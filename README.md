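# elevox

County-level ecological regression of cancer incidence on
population-weighted elevation.

Atmospheric pressure — and with it the partial pressure of inhaled
oxygen — declines almost linearly over habitable elevations, which makes
county elevation a natural dosage gradient for any inhaled, ubiquitous
carcinogen. `elevox` implements the full analysis pipeline for asking
whether age-adjusted cancer incidence falls with elevation once
demographic and risk covariates are accounted for, and whether the
association is specific to the directly exposed tissue (lung) rather
than non-respiratory sites (breast, colorectal, prostate). It is aimed at
epidemiologists and biostatisticians working with compiled county tables
and raster exposure surfaces.

## What it computes

* **Exposure**: population-weighted county exposure to a raster variable,
  `sum(pop_b * mean_b) / sum(pop_b)` over subunit (blockgroup) zonal means,
  with a deterministic half-open cell-center inclusion rule. Plain-text
  formats: ESRI ASCII grid rasters, GeoJSON subunits.
* **QC**: the county filters (state allow-list, population ≥ 10,000,
  immigration ≤ 40%, Native American composition ≤ 25%) and a binned
  absolute-residual divergence diagnostic for threshold selection.
* **Weighted regression**: weights `sqrt(min(pop, 250000))`; WLS with
  one-tailed inference; coefficients raw, standardized (β_z) and as a
  percentage of mean incidence (β_%); partial regression with partial R²
  (Frisch–Waugh–Lovell slope identity is tested to 1e-8).
* **Selection**: exhaustive best-subset search with the exposure forced
  in, optimised by `BIC = n·ln(RSS_w/n) + (k+1)·ln(n)`; weighted lasso
  (cyclic coordinate descent) with seeded 10-fold cross-validation and the
  one-standard-error rule.
* **Stratification**: smoking terciles, a standardized product interaction
  term, state-stratified models pooled by fixed-effects meta-analysis with
  Cochran's Q, I² and a Q-profile I² confidence interval, and
  population-subgroup refits.
* **Substitution**: forced replacement of the exposure by each of seven
  environmental correlates, compared through Bayes factors
  `K = exp(-ΔBIC/2)` at matched n; radon/UVB confounding triplets.
* **Synthetic counties**: a calibrated generator (Gaussian copula with a
  five-factor correlation structure, heteroscedastic noise tied to the
  weights, MCAR missingness, per-state slope heterogeneity) so every stage
  is testable offline with known ground truth.

## Worked example

```r
library(elevox)

sim    <- simulate_counties(sim_spec(seed = 1))  # 414 study-like counties
report <- run_all(sim$counties, seed = 1)
report
#> <elevox_report>
#>  counties: 414 -> 244 after QC
#>  optimal best-subset models:
#> # A tibble: 4 x 7
#>   cancer         n  size r_squared    beta   beta_z  p_value
#>   <chr>      <int> <int>     <dbl>   <dbl>    <dbl>    <dbl>
#> 1 lung         238     5     0.712 -8.31   -0.433   5.91e-26
#> 2 breast       230     6     0.628  0.0500  0.00257 5.24e- 1
#> 3 colorectal   228     6     0.491 -0.0679 -0.00820 4.34e- 1
#> 4 prostate     244     2     0.161 -2.94   -0.0951  5.44e- 2
#>  state meta-analysis: pooled -9.91 [-11.71, -8.10], I2 = 68%
```

Reading the output: of 414 generated counties, 244 survive quality
control. The BIC-optimal lung model keeps five predictors and estimates
that lung incidence falls by 8.3 cases per 100,000 per kilometre of
elevation (β_z = −0.43, one-tailed p ≈ 6e−26) — the generator's true
standardized elevation effect is −0.35, on lung only, and the 99% interval
covers the generating slope. The non-respiratory cancers show no
significant elevation association. Pooling the eleven state-specific
models gives −9.9 per km with I² ≈ 68%, reflecting the per-state slope
heterogeneity the generator injects.

Downstream surfaces are tibbles and plots:

```r
glance(report$subset$lung)          # optimal model summary
tidy(report$lasso$lung)             # lasso coefficients (beta_z, raw, %)
report$substitution$breast          # Bayes factors per candidate
autoplot(report$subset$lung)        # BIC trace across model sizes
autoplot(report$partial$lung)       # partial regression plot
autoplot(report$meta)               # state forest plot
write_report(report, "report_tsv")  # one TSV per table
```

On this run the breast substitution scan favours precipitation over
elevation (K ≈ 23), while every environmental substitute for the lung
model is at least 10^14 times less likely (all K < 1e−8) — the designed
contrast between an indirect, climate-mediated association and a direct
one.

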