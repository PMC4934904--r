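---
title: "Landscape pattern trends from annual forest change time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Landscape pattern trends from annual forest change time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forestpattern)
```

## The problem

Boreal forest landscapes are shaped by large, infrequent stand-replacing
disturbances (fire, clearcut harvest) and by slow recovery. How the spatial
*pattern* of forest — not just its amount — has changed over recent decades
is a central question for ecosystem-based management, which uses the
historical range of variability of landscape structure as its benchmark.
`forestpattern` implements a complete, testable pipeline for that question:
from annual spectral composites, through per-pixel change trajectories and
binary forest maps, to four landscape pattern indices tracked over time and
summarised with robust trend statistics.

Because the satellite archive behind such analyses is far too large to ship
with a package, every stage here is exercised on *synthetic* scenes whose
statistical structure mirrors the assumptions of the analysis. The simulator
is first-class, tested code: it is the package's source of ground truth, and
parameter recovery on its scenes is the package's acceptance standard.

## The simulated world

`sim_config()` + `generate_truth()` + `render_spectral()` produce a scene
with:

* an initial forest mask from a thresholded smoothed Gaussian random field
  (threshold set by quantile, so the target forest fraction is hit almost
  exactly), plus static water bodies from a second field;
* annual stand-replacing disturbance patches. Sizes follow a truncated
  discrete power law `P(s) ∝ s^-alpha` on `[min_patch_px, max_patch_px]` —
  the inverse size–frequency relationship characteristic of boreal fire
  regimes. The family and exponent are configuration, not estimated values;
  no disturbance-size parameters are claimed from any particular region.
  Patches are grown by uniform random frontier annexation (8-neighbour
  region growing), which yields irregular blobs with realistic
  perimeter/area variation — important for edge-density behaviour;
* an unbiased annual area target: patches are added until the expected
  disturbed area (`annual_disturbance_rate` × current forest) is reached,
  with the final overshooting patch accepted with probability
  `(target − accumulated)/size`. Long-run realized rates are therefore
  unbiased, while single years fluctuate by about half a mean patch size;
* linear spectral recovery: a disturbed pixel sits at the disturbed class
  means for `recovery_lag` years, then regains `recovery_rate` of its
  spectral deficit per year in every layer. The truth map returns the pixel
  to forest in the year its noise-free NBR ramp re-crosses
  `recovery_target` (default 80%) of the pre-event level — exactly the
  criterion the detector applies spectrally, so truth and detection share
  one definition of recovery;
* Gaussian layer noise and i.i.d. no-data gaps (`gap_prob`), consistent
  across layers within a year.

Default spectral class means (Tasseled-Cap brightness/greenness/wetness,
NBR, NDVI in reflectance-index units) are plausible for boreal forest, open
land and water but are deliberately generic. The disturbance contrast
defaults shift brightness +0.04 and greenness/wetness −0.04: with the
default per-layer noise SD of 0.02 that is a standardized disturbance-index
step of about 6, comfortably above the magnitude threshold of 5, with DI
noise (SD √3 ≈ 1.73) under a third of the contrast — the "moderate noise"
regime in which the detector is expected to be reliable.

What the simulator does **not** emulate: topography and illumination
effects, sensor cross-calibration drift, mixed- and low-severity
disturbance, insect defoliation, phenology within the season, spatially
correlated cloud masks, or gradual regrowth curves (recovery is linear).
Passing tests therefore demonstrate the internal correctness and
calibration of the pipeline under its own assumptions — not accuracy on any
particular real archive.

## Compositing and validity

`season_window()` centres the compositing season on day 209 (July 28, the
boreal peak-NDVI day) with length `L = a + b·latitude`; the default
coefficients (a = 339.5 d, b = −3.9 d/degree) reproduce start days between
May 7 and June 15 and end days between September 9 and October 18 across
latitudes 45–65. `score_candidate()` combines four terms in `[0,1]` —
preferred sensor, distance-to-cloud (Gaussian beyond a hard 50 m buffer,
with the 50 m buffer doubling as the Gaussian scale), day-of-year (Gaussian
with σ = window length / 4), and opacity (decreasing Gaussian, scale 0.2).
The published scoring scheme names these terms but prints no weights, so
weights are equal by default and configurable. `composite_year()` takes the
arg-max per pixel, breaking ties by earlier acquisition day then lower
opacity so results are deterministic.

Gap handling follows two rules. Interior gaps are interpolated linearly
between the two nearest data years bracketing the gap (reading "between the
two most recent years with data" as bracketing interpolation: backward-only
extrapolation would bias recovery trends); leading/trailing gaps extend the
nearest value. Pixels with ≥3 consecutive gap years or >6 total gap years
are excluded outright and become background everywhere downstream.

## Change detection

The disturbance index is `DI = Bz − (Gz + Wz)`, each component standardized
against a per-year forest reference sample. With no externally trained
forest mask available, the reference sample is self-calibrated: provisional
statistics over all valid pixels in year one give a provisional DI, pixels
with `|DI|` below the threshold form the sample, and per-year statistics
are recomputed over it. Reference standard deviations are floored at 1e-8
so that spectrally homogeneous (noise-free) scenes remain well defined;
`disturbance_index()` itself rejects user-supplied zero SDs as degenerate.

Trajectory rules, per pixel:

* **changed** — a run of at least `min_consecutive_years` (3) years with
  `DI` above the threshold (default 2 standardized units; the boreal
  calibration behind published maps is not public, so this is
  configuration) *and* run peak minus pre-run baseline greater than the
  magnitude threshold (5). The baseline is the mean DI over the years
  before the run (0 — the standardized forest expectation — when the run
  opens the series). The change year is the first year of the qualifying
  run; with several qualifying runs only the most recent is kept.
* **persisting non-forest** — `|DI|` outside the threshold band in *every*
  year. The band is two-sided because DI deviates from zero in either
  direction for non-forest surfaces; water, for example, sits far on the
  negative side.
* **persisting forest** — everything else.

Recovery is spectral: the threshold is `recovery_fraction` (80%) of the
mean NBR over the two pre-disturbance years (a single pre-year is used,
flagged, when the change is in year two; a change in year one has no
pre-year and recovery is left undefined), and the recovery year is the
first later year at or above it in the gap-filled NBR series. A single
crossing suffices — no multi-year persistence is required of recovery.

## Maps, landscapes and the four indices

Annual maps follow directly from the states; the minimum mapping unit of
1 ha is enforced with the 8-neighbour rule in two passes — sub-MMU
non-forest patches to forest first, then sub-MMU forest patches to
non-forest. At the 0.09 ha grain, 12 pixels (1.08 ha) survive and 11
(0.99 ha) do not. The pass order is fixed for determinism; for pathological
salt-and-pepper mosaics the reverse order can differ, which is why the
filter's idempotence and area bounds are property-tested.

Landscapes are square, non-overlapping windows at nominal extents of 5,000,
10,000, 25,000 and 50,000 ha (sides 236, 333, 527, 745 px at 30 m); partial
windows at scene margins are dropped. A landscape is retained when
background ≤ 25%, zone coverage ≥ 10% and agricultural influence ≤ 1%, each
rejection carrying its reason.

The four class-level indices per landscape-year:

* **forest cover** = 100 × forest pixels / landscape pixels;
* **largest patch index (LPI)** = 100 × largest 8-connected forest patch /
  landscape pixels;
* **edge density** = total forest patch perimeter (m) / landscape area
  (ha), counting every forest cell face not shared with forest — faces
  against non-forest, background, and the window boundary (patch-perimeter
  semantics; a boundary-free convention is available via
  `include_boundary = FALSE`, since edge-density conventions differ between
  implementations);
* **core forest cover** = 100 × forest pixels whose centre lies strictly
  more than 120 m (four pixels) from the nearest non-forest, background or
  outside-window pixel centre / landscape pixels. Euclidean distance is the
  default; a Chebyshev (4-pixel erosion) alternative is provided because a
  "four pixel" edge depth supports either reading.

Two denominator decisions matter and are deliberate: background (no-data)
pixels are excluded from landscape area, while water is included — water is
persistent non-forest land cover, an ecological feature of stable
landscapes, not missing data. Consequently `core ≤ cover` and
`LPI ≤ cover` always, and an all-forest window has non-zero edge density
and core below 100% (the boundary is edge).

## Trend and autocorrelation statistics

`mann_kendall()` implements the tie-corrected test: `S = Σ sign(x_j − x_i)`
over pairs, tau-b, the tie-corrected variance of `S`, and a two-sided
normal p-value with continuity correction; constant series return tau 0,
p 1 rather than an error. `theil_sen()` is the median of all pairwise
slopes with median-residual intercept. Both are verified against
exhaustive pairwise oracles, and the test's empirical size at α = 0.05 is
checked on i.i.d. Gaussian series of the study length (n = 26).

Confidence intervals for tau use a circular moving-block bootstrap
(B = 500): blocks of 3 consecutive years are drawn with replacement,
ordered by their original position so replicates preserve the series' time
order, concatenated to length n, and the percentile interval of the
replicate taus is reported. Block length 3 was chosen because the temporal
autocorrelation of these index series is material for up to two annual
lags, so 3-year blocks span the dependent range; percentile (rather than
BCa) intervals keep the procedure simple and deterministic.

Stratum (ecozone-like) summaries take two complementary views: the
Mann-Kendall test and Theil-Sen line on the annual cross-landscape median
series, and the median of per-landscape Theil-Sen slopes with a bootstrap
percentile interval over landscapes (1,000 repetitions, seeded). Strata
with fewer than five landscapes are flagged.

`classify_change()` reproduces the three-way partition: landscapes with a
non-significant cover trend (p ≥ 0.05) are *no change*; significant
landscapes are *high* magnitude at or above the 90th percentile of slope
magnitude and *moderate* below it. Ranking uses `|slope|` by default —
change in this setting is overwhelmingly decline, and magnitude matches
the class labels — with signed ranking as an alternative; the percentile is
the linear-interpolation quantile with an inclusive upper tail, so 100
significant landscapes yield exactly 10 high-magnitude ones.

Spatial structure is summarised by a Moran's I correlogram over half-open
centroid-distance bins (each unordered pair counted in exactly one bin);
bins need at least 1,000 pairs. The "large-lag standard error" is
operationalized as the square root of the randomization-null variance of
Moran's I for the bin's binary weight matrix (the closed-form
permutation-null variance); a bin is significant when
`|I − E[I]| > 2·SE` with `E[I] = −1/(n−1)`. A Bartlett-style cumulative
formula is a noted alternative; the randomization variance was chosen
because it is exact for the statistic actually computed per bin. Distances
are planar, on projected coordinates.

Temporal autocorrelation uses the standard single-mean, biased-denominator
estimator (`stats::acf`), stable at n = 26. A lag is significant across
landscapes when the interquartile range of per-landscape `r_k` lies
entirely outside ±2 standard errors of the mean correlation.

## Numerical choices and degenerate inputs

* Reference-SD floor 1e-8 (noise-free scenes); zero-variance series are an
  error for Moran's I (undefined statistic) and a flagged `NA` for the
  temporal ACF.
* Ties in compositing broken by day then opacity; ties in patch sizes need
  no breaking (all sub-MMU patches are reclassified).
* Pixel indices are 0-based row/column offsets with half-open windows;
  projected coordinates refer to pixel centres, y increasing upward.
* Rasters are stored as multi-page 32-bit float TIFF with an affine [0,1]
  encoding per layer and a JSON sidecar for grid metadata; round-trips are
  exact to float32 quantization of each layer's range (about 1e-7
  relative), and forest maps round-trip bit-exactly.
* All randomness flows from a single seed; identical configurations give
  bit-identical scenes, tables and files.

## Problem sizes used by the tests

The packaged experiments run on desk-scale scenes chosen to exercise every
rule while keeping the suite quick: oracle equivalence on ≥100 random maps
up to 64×64; trend-statistic oracles on 500 series of length ≤12; test
calibration on 10,000 series of length 26; end-to-end parameter recovery on
472×472-pixel scenes (a 2×2 grid of 5,000 ha landscapes) over 26 years with
an injected decline of −0.10% of landscape area per year, across 20 seeds;
and detection-quality checks on 236×236 scenes with recovery enabled. The
acceptance script (`scripts/acceptance.R`) re-runs the same experiments
from scratch at 10 replicate scenes.

## Known limitations

Detection is blind to events in the final two years of a series (the
three-consecutive-year rule cannot be satisfied), which slightly attenuates
measured decline rates relative to truth — visible in the parameter
recovery experiment and inherent to the rule, not a defect. Low- and
mixed-severity change is out of scope by design (the magnitude threshold
suppresses it). The self-calibrated forest reference assumes forest
dominates the year-one scene within the DI band. The simulator's
independence assumptions (i.i.d. gaps, white layer noise) are optimistic;
real archives have structured gaps and correlated noise, so real-data
performance must be validated separately.
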