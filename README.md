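# thermozone

Bioclimatic zoning for sheep farming from kriged temperature–humidity
index (THI) surfaces.

Heat stress limits sheep productivity and welfare, and the critical THI
at which an animal becomes stressed differs by breed — hair breeds
tolerate higher THI than wool breeds. Given a multi-year table of
gridded annual climate (maximum and minimum air temperature, mean wind
speed), thermozone maps where each breed can be farmed:

1. **THI** per grid point and year, using the sheep-calibrated
   wind-adjusted form
   `THI = (6.3952 + 0.08964 Tair + 0.01018 Ws)^2` with
   `Tair = (Tmax + Tmin)/2`;
2. **descriptive statistics** per year: five-number/boxplot summaries,
   coefficient-of-variation classes (low < 12% ≤ medium ≤ 24% < high),
   Lilliefors-corrected Kolmogorov–Smirnov normality at the 1% level;
3. **spatial structure**: empirical semivariograms `γ̂(h) = Σ(zᵢ−zⱼ)²/2N`
   and iteratively reweighted Cressie-weighted fits of spherical,
   exponential and Gaussian models, with the degree of spatial
   dependence `100·nugget/sill` (< 25% strong, 25–75% moderate, > 75%
   weak);
4. **ordinary kriging** surfaces with kriging standard errors, and
   leave-one-out cross-validation (ME, MAE, standardized mean error,
   ASE, RMSE, RMSSE) driving model selection by `|RMSSE − 1|`;
5. **zoning**: per-breed suitability masks (`THI ≤ limit`, inclusive)
   against a packaged registry of 21 Brazilian sheep breeds, area
   fractions per subregion, and regional empirical CDFs by quadrennial.

A stationary Gaussian random-field simulator with prescribed
nugget/sill/range generates synthetic climate series over a partitioned
study region, so the full pipeline runs and is testable offline. The
package is intended for animal-biometeorology and agro-environmental
analysts working in R.

## Worked example

Simulate one year of climate over the demonstration region (a 204 km ×
48 km window on a 4-km lattice, 676 points, five mesoregion bands), and
run the stages by hand:

```r
library(thermozone)
region <- demo_region()
climate <- simulate_climate_series(
  region, years = 2010,
  tmax_params = field_params(29, "gaussian", nugget = 0.11, sill = 1.4,
                             range_m = 60000, trend = c(0.01, 0)),
  tmin_params = field_params(24, "gaussian", nugget = 0.11, sill = 1.4,
                             range_m = 60000, trend = c(0.01, 0)),
  ws_params   = field_params(2, "gaussian", nugget = 0.02, sill = 0.2,
                             range_m = 60000),
  seed = 42)
thi <- annual_thi(climate)
summary_stats(thi$thi, year = 2010)
#>   year   n mean median  min  max   sd cv_pct cv_class skewness kurtosis_excess
#> 1 2010 676 76.4   76.6 72.7 79.5 1.45   1.89      low    -0.46          -0.345
```

The field is homogeneous (CV ≈ 1.9%, "low"). Fit the three variogram
families and cross-validate:

```r
emp <- empirical_semivariogram(cbind(thi$x_m, thi$y_m), thi$thi)
fits <- lapply(c("spherical", "exponential", "gaussian"),
               function(f) fit_variogram(emp, f))
reports <- do.call(rbind, lapply(fits, function(vm) {
  loo <- loo_predict(thi, vm)
  cv_statistics(loo$observed, loo$predicted, loo$sigma, 2010, vm$family)
}))
reports
#>   year      family        me   mae   mse_std   ase  rmse rmsse   n
#> 1 2010   spherical -0.000814 0.338 -0.000837 0.425 0.430 1.010 676
#> 2 2010 exponential -0.000728 0.338 -0.000616 0.516 0.430 0.833 676
#> 3 2010    gaussian -0.000488 0.312 -0.000657 0.339 0.392 1.159 676
```

All three models are nearly unbiased (ME ≈ 0); the RMSSE closest to 1
wins (here the spherical fit, at 1.010 — on a single synthetic year the
families are often near-indistinguishable; see the methods vignette).
Krige the surface with the selected model and zone it:

```r
sel <- select_model(reports)
best <- fits[[match(sel$family, sapply(fits, `[[`, "family"))]]
kr <- predict_grid(thi, best, region)
zone <- suitability_masks(kr)
zone$summary[c(1, 9, 21), c("breed", "cover", "thi_limit", "area_pct", "usable_regions")]
#>         breed cover thi_limit  area_pct                                               usable_regions
#> 1  Rabo Largo  hair     81.93 100.00000 Sao Francisco; Sertao; Agreste; Zona da Mata; Metropolitana
#> 9        SAMM  wool     75.92  32.24852
#> 21  Hampshire  wool     71.99   0.00000
cd <- regional_cdf(thi, "Agreste", 2010)
cdf_at(cd, 77)
#> [1] 0.3230769
```

Rabo Largo (limit 81.93) is usable everywhere; SAMM only on 32% of the
territory; Hampshire (71.99) nowhere in this warm simulated year. The
whole pipeline — all years, all families, rasters and reports written as
plain-text files, byte-identical across re-runs with the same seed — is
one call:

```r
run_all(demo_config(years = 2010:2012, seed = 1), "out/")
```

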