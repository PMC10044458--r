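---
title: "Geostatistical THI zoning: models, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geostatistical THI zoning: models, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

thermozone maps livestock heat-stress risk from gridded climate data. The
pipeline has five scientific stages: a temperature–humidity index (THI)
computed per grid point and year; descriptive statistics of each annual
field; a semivariogram analysis of its spatial structure; ordinary kriging
of continuous THI surfaces with leave-one-out cross-validation for model
selection; and classification of the surfaces into per-breed sheep
suitability zones. A Gaussian random-field simulator generates synthetic
multi-year climate series so the whole pipeline runs and is testable
without any remote-sensing download. This vignette records the models, the
parameter choices that matter, and the places where the design was
genuinely open.

## The index

The THI variant used here is a quadratic in mean air temperature with a
small wind-speed adjustment,

$$\mathrm{THI} = (6.3952 + 0.08964\,T_{air} + 0.01018\,W_s)^2,$$

with $T_{air}$ in °C and $W_s$ in m s⁻¹. Despite the name, this form
carries no humidity term; it was calibrated for sheep and is strictly
increasing in both arguments over the physical domain (both linear
coefficients and the base are positive there). Higher values mean a more
stressful thermal environment; published critical limits for Brazilian
sheep breeds span 71.99–81.93.

Two conventions are worth stating because the upstream data products leave
them open:

* $T_{air} = (T_{max} + T_{min})/2$. Gridded climate products ship daily
  extremes, not means; the arithmetic mid-range is the standard
  convention and matches the magnitudes of the region (annual means of
  24 and 29 °C give $T_{air} = 26.5$).
* The annual THI is the **index of the annual means** — one evaluation of
  the formula per point-year — not the mean of monthly THI values. The
  formula is nonlinear, so the two differ by Jensen's-inequality terms;
  the index-of-means reading matches how annual summaries of this index
  are usually reported. `annual_thi()` implements it; computing a
  monthly-mean variant is a matter of aggregating before or after calling
  `compute_thi()`.

## Descriptive statistics

`summary_stats()` reports mean, median, extremes, sample (n−1) standard
deviation, the coefficient of variation with the agronomic low/medium/high
classes (boundaries at 12% and 24%, both inclusive to medium), and
bias-corrected sample skewness and excess kurtosis (the conventions under
which a normal sample scores ≈ 0, delegated to `e1071` type-2
estimators). Normality is tested with the one-sample Kolmogorov–Smirnov
test against a normal with estimated parameters; because the parameters
are estimated from the same sample, the Lilliefors correction is applied
(`nortest::lillie.test`) — the uncorrected KS p-value would be strongly
anti-conservative. The significance level defaults to 1%. Quartiles and
boxplot fences use linear interpolation of order statistics (quantile
type 7) and Tukey's 1.5·IQR rule.

## Spatial structure

The empirical semivariogram (`empirical_semivariogram()`) is the binned
method-of-moments estimator
$\hat\gamma(h) = \frac{1}{2N(h)}\sum (z_i - z_j)^2$ over point pairs
whose separation falls in right-closed bins of equal width. Defaults: 12
bins up to half the maximum pairwise distance. Two details:

* The lag position reported for each bin is the **mean pair separation**
  within the bin, not the nominal bin center. On lattice data the
  distinction matters: the first bin's nominal center can sit below the
  minimum pair distance, which misplaces the near-origin points and
  biases the fitted nugget.
* Zero-distance pairs (duplicate coordinates) are excluded with a
  warning; the estimator is defined for $h > 0$.

Three bounded models are supported — spherical, exponential and Gaussian —
in the practical-range parametrisation (the −3 exponent scaling), with
$\gamma(0) = 0$ exactly and the nugget as a jump at the origin. "Sill"
always means the **total** sill $C_0 + C$; the degree of spatial
dependence is $100\,C_0/(C_0+C)$, classified strong below 25%, moderate
to 75%, weak above.

`fit_variogram()` minimises the Cressie-weighted squared error
$\sum_k N_k\,(\hat\gamma_k - \gamma_k)^2/\gamma_k^2$ by iteratively
reweighted bounded least squares: the weights are frozen at the current
model per solve and the solve repeated to a fixed point. Minimising
jointly over parameter-dependent weights is subtly wrong — the objective
can be lowered by inflating the model semivariance — and measurably
biases the fitted sill upward. Numerical choices: parameters are
optimised in scaled units (semivariances relative to the empirical
maximum, distances relative to the largest lag) because the raw scales
differ by five orders of magnitude; three starts (method-of-moments,
near-flat, steep short-range) guard against local minima; the range is
bounded below by the shortest observed lag and above by the largest —
outside that window it is not identifiable from the data, and an
unbounded fit occasionally extrapolates meaningless sills at ranges far
beyond the lag span. A flat empirical variogram is genuinely ambiguous
(any split between nugget and sub-lag-range structure fits equally
well); near-exact ties are resolved toward the larger nugget, i.e. read
as absence of spatial structure, which is the standard geostatistical
interpretation and puts the degree of spatial dependence near 100%
rather than near 0%.

## Kriging and cross-validation

`predict_grid()` implements ordinary kriging in semivariogram form: the
augmented system with a unit unbiasedness row, zero diagonal (the whole
nugget lives in $\gamma(h>0)$; no measurement-error split), and kriging
variance $\sum_i w_i\gamma_{i0} + \mu$. Consequences of this convention:
prediction at a sample location reproduces the sample exactly with zero
kriging variance (the implementation also short-circuits that case), and
weights sum to 1 to machine precision. The default neighborhood is
global — at the desk scales this package targets (≤ a few thousand
points) one factorization serves every cell; a local
`list(max_n=, radius_m=)` neighborhood mirroring common GIS practice is
available. The output lattice defaults to the 4-km input spacing, and
surfaces serialise to ESRI ASCII grids with a −9999 no-data sentinel.

Leave-one-out cross-validation (`loo_predict()`) keeps the variogram
fitted once on the full data — refitting per fold is ~n× costlier and is
not what GIS cross-validation tools do. Each fold is computed from a
single inverse of the covariance-form augmented matrix via Dubrule's
identity ($\hat z_{-i} = z_i - (Bz)_i/B_{ii}$,
$\sigma_i^2 = 1/B_{ii}$), which is exact for bounded variograms; the
test suite re-verifies it against per-fold re-solves. The six error
statistics follow the conventional GIS cross-validation table: ME, MAE,
a **signed** standardized mean error (traditionally labelled "MSE" in
those tables despite not being a squared quantity), ASE as the plain
mean of the kriging standard errors, RMSE, and RMSSE. Model selection
ranks families by $|\mathrm{RMSSE} - 1|$ (calibration of the kriging
variances), breaking near-ties (within 10⁻⁶) by $|\mathrm{RMSE} -
\mathrm{ASE}|$, then $|\mathrm{ME}|$, then a fixed family order, so the
winner never depends on input order.

## The synthetic generator and what it does (not) show

`simulate_gaussian_field()` draws stationary Gaussian fields by dense
Cholesky factorization of the covariance $C(h) = \mathrm{sill} -
\gamma(h)$ implied by a chosen variogram, with a $10^{-10}\cdot$sill
diagonal jitter and a 5000-point guard. `simulate_climate_series()`
composes three independent fields per year (maximum temperature, minimum
temperature, wind speed), truncates wind speed at zero and clips
$T_{min} \le T_{max} - 0.01$ °C. Coordinates are planar meters in a
local frame so all distances are Euclidean; real exported data must be
projected before use.

The default study conditions mirror the semiarid-state setting the
package was built around: a 204 km × 48 km window on a 4-km lattice
(52 × 13 = 676 points) split into five west–east bands named after
Pernambuco's mesoregions — the elongated shape mirrors the state's
geometry so spatial ranges near 60 km fit inside the window; temperature
means of 29/24 °C (the region's stated annual extremes), wind 2 m s⁻¹;
Gaussian spatial structure with range 60 km and variances chosen so the
derived THI field has sill ≈ 1.7 and nugget ≈ 0.13, the magnitudes of
published annual-THI variogram fits for the state; and a gentle 0.01
°C km⁻¹ eastward warming trend in the demo configuration. Simulations in
the test and acceptance suites use these 676-point conditions with 10
seeds, which keeps the full suite within a few minutes on one CPU.

What passing tests show — and what they do not:

* Exactness properties (estimator identities, kriging algebra, THI
  arithmetic) are checked against independent brute-force oracles and
  hold regardless of the generator.
* Calibration properties (10-seed mean RMSSE of the correctly specified
  model within [0.8, 1.2]; nugget/sill/range recovered within ±30% on a
  10-seed average) are properties of these study conditions. The window
  is only ~3.4 ranges long, so a single realisation carries few
  independent patches; per-seed fitted sills scatter widely and skew
  right, and the +20–25% average sill excess observed across seed sets
  is sampling skew, not estimator bias (the mean empirical semivariogram
  matches the true model to within a few percent).
* Model-family discrimination is **weak** under these conditions: with a
  genuine nugget in the simulated covariance, misspecified spherical or
  exponential fits also calibrate to RMSSE ≈ 1.0–1.2, and the
  $|\mathrm{RMSSE}-1|$ criterion picks the generating Gaussian family in
  only about half the seeds (5–9 of 10 across disjoint seed sets). The
  sharp discrimination seen in real smooth remote-sensing fields — where
  the alternatives score RMSSE 0.5–0.7 — arises because such fields have
  far less true micro-scale variance than their fitted nuggets imply, so
  misspecified models overstate the kriging variance. The generator,
  which takes the fitted parameters as the true covariance, deliberately
  does not emulate that discrepancy; a passing selection test here would
  therefore say little, and a failing one says nothing, about real-data
  performance.
* Real data differ in further ways the generator ignores: cross-
  correlation between the three climate variables, between-year
  persistence, non-Gaussian tails, anisotropy, and irregular state
  borders.

## Zoning

A breed is suitable at a cell when the kriged THI does not exceed its
critical limit (inclusive: a breed at exactly its limit is "working at"
its threshold, not beyond it). The packaged registry carries the 21 main
Brazilian sheep breeds (7 hair, 14 wool; limits 71.99–81.93, names
ASCII-folded). A breed is "usable" in a subregion when 100% of the
subregion's valid cells are suitable; `min_fraction` relaxes that,
because near-misses (e.g. 95% coverage) are often the practically
interesting cases, and the per-subregion percentages are always
reported. Regional empirical CDFs pool point-year values per subregion
over configurable periods (default quadrennials: 2010–2013, 2014–2017,
2018–2021) and evaluate inclusively ($P(\mathrm{THI} \le t)$) by
default.

## Pipeline and reproducibility

`run_all()` orchestrates the stages from a single configuration list (or
YAML file): simulate or read climate, validate (rows violating
$T_{max} > T_{min}$ or $W_s \ge 0$ are rejected, with a hard error above
50% rejections), THI, per-year summaries, all families fitted and
cross-validated per year, selection, kriged surfaces, zoning and CDF
reports. Every output is plain text; report tables are rounded at write
time (2 decimals for THI summaries, 6 for cross-validation and variogram
parameters) while `thi.csv` keeps full precision; the run log carries no
timestamps. A run is a pure function of (configuration, seed):
re-running reproduces every file byte-identically, which the test suite
asserts. There is no shell entry point — the exported functions are the
interface, and `scripts/acceptance.R` shows a complete scripted run.

## Known limitations

* Isotropic, single-structure variograms only; no anisotropy, nesting,
  or trend (universal) kriging. The simulator's linear trend option is
  useful precisely for studying how a modest trend inflates apparent
  sills.
* Dense linear algebra throughout: ~5000 points for simulation and a few
  thousand samples for global-neighborhood kriging are the practical
  ceilings.
* The THI form is breed-calibration-specific and humidity-free;
  conclusions transfer to other indices only qualitatively.
* Real-data ingestion expects metric planar coordinates; no projection
  machinery is included.
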