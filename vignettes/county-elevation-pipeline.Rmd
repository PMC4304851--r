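---
title: "Methods: county-level ecological regression of cancer incidence on elevation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: county-level ecological regression of cancer incidence on elevation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elevox)
```

## The scientific question and the estimand

Atmospheric pressure — and with it the partial pressure of inhaled oxygen —
falls nearly linearly across habitable elevations, so county elevation acts
as a natural dosage gradient for a candidate inhaled carcinogen. The
pipeline in this package estimates the association between
population-weighted county elevation and age-adjusted cancer incidence
(cases per 100,000 per year), contrasting a respiratory site (lung) with
non-respiratory sites (breast, colorectal, prostate). The estimand of
interest is the multivariate elevation coefficient in a weighted linear
model of county incidence: cases per 100,000 per kilometre of elevation,
reported alongside its standardized form ($\beta_z$) and as a percentage of
mean incidence ($\beta_\%$).

This is an ecological design: counties, not people, are the units, so any
association is a population-group association and the usual ecological
fallacy caveat applies throughout.

## Weighted least squares core

Counties are weighted by $w_i = \sqrt{\min(\text{pop}_i, 250{,}000)}$. The
square root reflects sampling noise in county rates shrinking with
population; the cap stops a few metropolitan counties from dominating.
`fit_wols()` minimises $\sum_i w_i (y_i - x_i^\top\beta)^2$, with
$\hat\sigma^2 = RSS_w/(n-k-1)$ and $t$-based inference on $n-k-1$ degrees
of freedom — at $n \approx 250$ the $t$ and normal references differ
visibly, and $t$ is the standard choice. A one-tailed p-value for
coefficient negativity ($P(T \le t)$) accompanies the two-sided one,
matching the directional hypothesis; the familywise cutoff across the four
cancers is Bonferroni-adjusted to $0.05/4 = 0.0125$.

Weighted means, sds and z-scores use the $\sum w$ (population) denominator
rather than a bias-corrected one. One convention has to be fixed; the
difference is $O(1/n)$, and the package applies it consistently so the
standardized coefficient from a raw fit equals the slope of the fully
z-scored fit to machine precision (a tested invariant).

Missing cells are blank in the tab-delimited interchange format and never
coerced to zero. Each cancer's fits run on its own dataset: the complete
cases over every variable included for that cancer, so the selection scan,
the lasso, the partial regression and the lung stratifications all share
one case set and their BICs and coefficients are mutually comparable.

## Model selection: forced-exposure best subset and the lasso

`best_subset()` enumerates, for every model size, all covariate subsets
that contain the forced exposure and keeps the weighted-RSS minimiser;
across sizes the optimum minimises
$BIC = n\ln(RSS_w/n) + (k+1)\ln n$ (additive constants omitted — only BIC
differences are consumed, for selection and for Bayes factors). With at
most 12 candidate covariates the search space is $2^{11}$ models;
exhaustive enumeration is exact, instantaneous, and testable against
brute-force oracles, so no branch-and-bound is used. Ties in BIC break
toward the smaller size, then lexicographic member order.

Exhaustive search over correlated predictors can overfit, so the package
pairs it with an L1-penalised fit. `cv_lasso()` minimises
$$\frac{1}{2\sum w}\sum_i w_i(y_i - \beta_0 - x_i^\top\beta)^2
  + \lambda\|\beta\|_1$$
on weighted z-scores by cyclic coordinate descent (soft-threshold updates
with covariance updating, warm starts along the grid, convergence when the
largest coefficient change falls below $10^{-7}$). The grid has 100
log-spaced points from $\lambda_{max}$ — the smallest penalty that zeroes
every coefficient, stored exactly so the top of the path is exactly empty —
down to $0.001\,\lambda_{max}$. The penalty is chosen by seeded 10-fold
cross-validation with the one-standard-error rule: the largest $\lambda$
whose CV error is within one between-fold standard error of the minimum.
Standardization is re-estimated inside each training fold (the alternative,
one global standardization, leaks the held-out scale into training and is
noted as a replication-tolerance source); held-out error is weighted by the
held-out counties' weights, consistent with the fitting loss. Every
solution on the grid satisfies the subgradient stationarity (KKT)
conditions to $10^{-6}$, a tested property, and the unpenalised end of the
path equals the weighted least-squares fit.

## Partial regression

For the focal exposure, `partial_regression()` reports the two residual
vectors of the partial regression plot and their weighted simple-regression
slope, which equals the multivariate exposure coefficient by the
Frisch–Waugh–Lovell theorem (asserted at $10^{-8}$). The partial
$R^2 = 1 - RSS_{full}/RSS_{-exposure}$ measures variance explained by the
exposure beyond the covariates; the bivariate $R^2$ of incidence on the
exposure alone is reported for contrast. Adjustment sharpening — partial
above bivariate — is the signature of covariates suppressing, not
producing, the association.

## Stratification, meta-analysis, subgroups

Smoking terciles use type-7 quantile interpolation at the 1/3 and 2/3
points with boundary values assigned to the lower stratum; the convention
is arbitrary but fixed, since published cutpoints only disambiguate to one
decimal. The smoking-by-elevation interaction is tested by appending the
product of the two weighted z-scores to the optimal model.

State-stratified models regress lung incidence on elevation and smoking
only (small within-state samples cannot carry the full covariate set), and
`fixed_effects_meta()` pools the per-state elevation slopes with inverse
variance weights. Heterogeneity is summarised by Cochran's $Q$ and
$I^2 = \max(0, 100(Q - df)/Q)$; the 95% interval for $I^2$ inverts the
generalised $Q$ statistic over the between-state variance (Q-profile) and
maps it to the $I^2$ scale through the typical within-state variance. A
random-effects model is deliberately out of scope: the fixed-effects pooled
value is the descriptive summary used here.

Population-subgroup refits (males, females, under 65, 65+) use the optimal
covariate set on counties complete across all four subgroup outcomes, with
sex-specific smoking prevalence swapped into the sex models. Coefficients
are reported on both the raw and standardized scales: subgroup outcomes
have very different dispersions (under-65 incidence is several-fold
smaller than 65+), so the two scales answer different comparability
questions and neither is privileged.

## Environmental substitution and confounding triplets

`substitution_scan()` asks whether any of seven environmental correlates of
elevation (radon, fine particulate, UVB, sunlight, precipitation, high
temperature, diurnal temperature range) explains an outcome better than
elevation does: each candidate is forced into its own best-subset search in
place of elevation and the change in optimal BIC becomes an approximate
Bayes factor $K = e^{-\Delta BIC/2}$, with $K > 1$ favouring replacement.
For lung, radon and particulate leave the covariate set and join the
candidate list. BICs are only comparable at identical $n$, so each
candidate's reference search is recomputed on the complete-case
intersection over the covariates, elevation and that candidate; the
package refuses to compare BICs across differing case sets.

The radon/UVB confounding triplets fit the variable with (1) smoking,
(2) smoking plus elevation, and (3) the optimal best-subset predictors,
reporting the variable's standardized coefficient with a 95% interval
(this table's convention, unlike the 99% used elsewhere) and the one-tailed
negativity p-value. The pattern of a strongly negative model-1 coefficient
erased in models 2–3 is the signature of elevation confounding.

## Population-weighted exposure over a raster

County exposure is the population-weighted mean of subunit (blockgroup)
zonal means: $\sum_b p_b \bar{x}_b / \sum_b p_b$. A raster cell contributes
to a subunit's zonal mean when its center lies inside the polygon; the
even-odd crossing test used is half-open (lower-left-inclusive), so
polygons tiling a region claim each cell center exactly once and refining a
partition never changes the county exposure (tested to $10^{-9}$). Partial
cells are not area-weighted. A subunit that captures no cell center — a
real scenario for small blockgroups against a 1-km grid — falls back to the
nearest cell's value with a warning.

Rasters are read and written as ESRI ASCII grid (`.asc`), a plain-text
single-band format with explicit georeferencing; subunit polygons travel as
GeoJSON with `subunit_id`, `county_id` and `population` properties. Inputs
must share one coordinate reference system; the module validates the tags
but never reprojects — geodesy is kept out of the statistical artifact.
Exact numeric replication of any particular GIS stack's county elevations
is not promised (cell-inclusion and partial-cell rules differ across
stacks); the framework, not a specific raster product, is the deliverable.

## The synthetic county generator

`simulate_counties()` exists so every stage is testable with no downloads,
and its defaults encode the study conditions the pipeline targets:

* **Marginals** follow the documented predictor table: means and sds for
  each of the 25 predictors (e.g. elevation 0.97 ± 0.74 km, smoking
  47 ± 5.8%), a Bernoulli(0.43) metropolitan indicator, log-normal
  immigration and Native American composition, and a log10-normal
  population chosen so that roughly 63% of 414 generated counties survive
  quality control (≈260).
* **Correlation** comes from a five-factor Gaussian copula
  (elevation/climate, socioeconomic, smoking/health, sun, demographic)
  whose loadings reproduce the documented landscape: radon–elevation 0.71,
  UVB–elevation 0.50, strongly collinear climate variables, all other
  elevation correlations below |0.55|. Only pairwise structure is
  constrained; higher-order joint structure is a free modelling choice and
  is multivariate normal here.
* **Effects**: lung incidence is generated from five predictors —
  standardized effects 0.59 (smoking), −0.35 (elevation), 0.10 (black),
  −0.15 (education), 0.20 (other-cancer incidence) — so the generating
  elevation slope is −0.35·14.4/0.74 ≈ −6.81 per km. Breast, colorectal
  and prostate carry **no** elevation effect; breast instead carries a
  small precipitation effect (+0.15 standardized), which induces exactly
  the indirect, climate-mediated elevation shadow that the substitution
  scan is designed to expose.
* **Noise** is heteroscedastic and tied to the analysis weights exactly,
  $sd(\varepsilon_i) \propto 1/\sqrt{w_i/w_{max}}$, making weighted least
  squares the efficient estimator; the level is calibrated so the weighted
  model $R^2$ on quality-controlled counties matches the documented fits
  (≈0.70 lung, 0.57 breast, 0.34 colorectal, 0.19 prostate).
* **State heterogeneity**: each state perturbs the lung elevation slope by
  a mean-zero normal deviate (sd 3.2 incidence units per standardized
  elevation, ≈4.3 per km), sized so the state meta-analysis exhibits the
  documented moderate-to-high heterogeneity ($I^2 \approx 70\%$).
* **Missingness** is completely at random, per column, at the documented
  per-predictor rates (the true missingness mechanism of compiled county
  data is unknown; MCAR is the neutral choice).

What the generator does **not** emulate: real geography (no county
adjacency, no state–elevation association), non-Gaussian dependence, and
any informative missingness. Tests passing on this generator therefore
demonstrate correctness of the estimators and the pipeline plumbing under
the stated statistical structure — not that any particular published point
estimate would be reproduced on the real compiled dataset, which is not
redistributed here. Reference-value checks run against a single seeded
realisation of ~260 counties and carry that sampling variability
(standardized-coefficient SEs around 0.04, plus the state-heterogeneity
component); they are asserted at the published tolerances and some are
expected to sit outside them on any given seed.

## Numerical and degenerate-input choices

* Constant (zero-weighted-variance) predictors are an error at
  z-scoring; rank-deficient designs raise a singular-design error naming
  the collinear columns; rank-deficient subsets inside the search are
  skipped with a warning.
* `BIC` at zero residual sum of squares is a guarded error rather than
  $-\infty$.
* QC thresholds are strict inequalities (a county at exactly 40%
  immigration or 25% Native American composition is retained), in units of
  percent, matching the table columns; rules apply in the fixed order
  state → population → immigration → Native American, first violation
  recorded.
* The divergence diagnostic (all-site incidence on eight demographic
  covariates, exposure deliberately excluded) summarises its absolute
  weighted residuals by ten equal-count bins rather than loess: binned
  means are oracle-testable and carry no smoothing parameters; thresholds
  remain a user decision.
* County tables may arrive with either a population column (weights are
  derived) or precomputed weights passed directly to every fitting
  function — both interfaces are supported.
* Test problem sizes were chosen to exercise every property at full
  strength while keeping the whole suite inside a few minutes: exhaustive
  brute-force equivalence at 12 predictors, correlation convergence at
  n = 50,000, coverage and stability properties at 100 seeded replicates
  of ~250–400 counties.

## Known limitations

Ecological associations cannot identify individual-level risk; the
pipeline quantifies and stress-tests a county-level association, nothing
more. The exposure module handles single-band rasters and exterior polygon
rings only, does not reproject, and does not support finer census-block
subdivision. The lasso's published-table reproduction is approximate by
design: fold assignment is seed-controlled but the original fold seed of
any given study is unknowable. National extrapolations (attributable cases
under counterfactual elevations) are out of scope, as is acquisition of
the underlying public databases.
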