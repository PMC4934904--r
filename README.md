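# forestpattern

Temporal trends of landscape pattern in boreal forest, from annual spectral
time series to robust trend statistics — with a built-in synthetic-scene
simulator so the whole pipeline is testable without any satellite archive.

## The problem

Boreal landscapes are shaped by large stand-replacing disturbances (fire,
harvest) and slow recovery. Managers who benchmark against the historical
range of variability need to know not just how much forest there is, but how
its *pattern* — patch structure, edge, interior habitat — has changed year
by year. `forestpattern` implements that analysis end to end:

1. **Simulate** (or read) annual spectral scenes: Tasseled-Cap
   brightness/greenness/wetness (B, G, W), NBR and NDVI layers with clouds
   and data gaps.
2. **Composite**: best-available-pixel scoring (sensor, cloud distance,
   day-of-year, opacity), linear gap interpolation, and exclusion of pixels
   with ≥3 consecutive or >6 total gap years.
3. **Detect change** with the disturbance index `DI = Bz − (Gz + Wz)`
   (components standardized against a self-calibrated forest reference).
   A pixel is *changed* after ≥3 consecutive years above the DI threshold
   with run peak − pre-run baseline > 5; pixels outside the two-sided DI
   band every year are *persisting non-forest*. Recovery is spectral: the
   first year NBR regains 80% of its two-year pre-disturbance mean.
4. **Map**: annual forest/non-forest maps, filtered to a 1 ha minimum
   mapping unit under the 8-neighbour rule.
5. **Measure pattern** on grids of square landscapes (5,000–50,000 ha):
   forest cover, largest patch index (LPI), edge density (m·ha⁻¹), and core
   forest cover (120 m edge depth) — each verified against brute-force
   oracles.
6. **Infer trends**: Mann-Kendall tests (tie-corrected tau-b, continuity
   correction), Theil-Sen slopes, circular block-bootstrap confidence
   intervals for tau, stratum medians with bootstrap intervals, Moran's I
   spatial correlograms with large-lag standard errors, temporal
   autocorrelation screening, and a no-change / moderate / high-magnitude
   classification at the 90th percentile of slope magnitude.

Everything user-facing takes and returns tibbles, chains with the pipe, and
has `autoplot()` / `tidy()` / `glance()` methods.

## Worked example

Simulate a 236×236-pixel, 26-year scene (one 5,000 ha landscape) with
moderate disturbance, run the full pipeline, and look at the trend of the
four indices:

```r
library(forestpattern)

sim <- sim_config(grid_rows = 236, grid_cols = 236, n_years = 26,
                  annual_disturbance_rate = 0.004, max_patch_px = 300)
cfg <- pipeline_config(sim = sim, extents = 5000,
                       autocorr = list(min_pairs = 1), seed = 42)
res <- run_pipeline(cfg, quiet = TRUE)

res$detection
#> # A tibble: 1 × 5
#>   n_events n_evaluable detection_rate commission_rate mean_year_error
#>      <int>       <int>          <dbl>           <dbl>           <dbl>
#> 1       75          71              1         0.00190           0.496

dplyr::select(res$classes, landscape_id, tau, p_value, sen_slope, class)
#> # A tibble: 1 × 5
#>   landscape_id    tau p_value sen_slope class
#>   <chr>         <dbl>   <dbl>     <dbl> <fct>
#> 1 E5000_001    -0.382 0.00669   -0.0869 high
```

All 71 injected disturbance events that could be evaluated were detected
(100%), with 0.2% commission on undisturbed forest and a mean change-year
error under half a year. The landscape's forest cover declines at a
Theil-Sen slope of −0.087 percentage points per year, the Mann-Kendall
trend is significant (p = 0.0067), and the landscape is classified
high-magnitude change (it is the only significant landscape in this
one-window example, so it sits at its own 90th percentile).

Per-index trends on the same run:

```r
for (ix in c("forest_cover", "lpi", "edge_density", "core_cover")) {
  t <- landscape_trends(res$index_table, ix, bootstrap = FALSE)
  cat(sprintf("%-13s slope %+.3f per yr\n", ix, t$sen_slope))
}
#> forest_cover  slope -0.087 per yr
#> lpi           slope -0.087 per yr
#> edge_density  slope +0.420 per yr
#> core_cover    slope -0.213 per yr
```

The fragmentation signature of disturbance outpacing recovery: cover, LPI
and core forest fall while edge density rises. `autoplot(res$index_table)`
draws the four trajectories; `plot_forest_map(res$maps, 2010)` maps the
final year.

Individual statistics are ordinary functions on vectors and tibbles:

```r
mann_kendall(c(3, 1, 4, 1, 5, 9, 2, 6))
#> Mann-Kendall: S = 11, tau = 0.400, p = 0.2125 (n = 8)
theil_sen(2 * (1:10) + 1)
#> Theil-Sen: slope = 2, intercept = 1 (n = 10)
```

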