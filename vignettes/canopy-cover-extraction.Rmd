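---
title: "Extracting green canopy cover from nadir plot images: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting green canopy cover from nadir plot images: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`canopycover` turns nadir RGB images of row-sown field-trial plots into
plot-level green canopy cover (CC) time series, and those time series into
genotype-level traits: spatially adjusted means (BLUEs), per-date broad-sense
heritability, smoothed growth curves, and 50%-CC closure and senescence
dates. This vignette explains the model behind each step, the parameters
that matter, and the design choices made where the method leaves room.

## The extraction pipeline

Images from a stationary overhead platform are not georeferenced: the plot's
position inside the frame drifts with the camera, and the plot axis is
rarely exactly horizontal. The pipeline therefore locates the plot in every
image from the image content itself, in five steps.

**1. Green-pixel segmentation** (`segment_green()`). A pixel is vegetation
when `G/R >= 1.10`, `G/B >= 1.10` and `G >= 10` on the 0-255 scale. Ratio
rules of this form are the standard colour-index approach for separating
green canopy from soil; the exact thresholds are exposed in
`color_ratio_params()` because lighting and sensor differences shift the
optimum. The defaults here were calibrated against this package's synthetic
renderer (Jaccard >= 0.95 against rendered ground truth), not against any
particular camera. Computation is floating point on raw 8-bit values with no
gamma correction; zero denominators count as ratio infinity, so a pure-green
pixel is always vegetation. Masks are written as lossless PNG: a lossy
JPEG round trip would corrupt a binary raster.

**2. Row detection** (`detect_rows()`). Before canopy closure, rows appear
as horizontal bands, so the y-coordinates of vegetation pixels are
multimodal regardless of gaps along x caused by incomplete emergence. The
detector builds a Gaussian kernel density of the green-pixel y-coordinates
(bandwidth `row_spacing/4` by default) and finds peaks at minimum separation
`row_spacing/2`. Pixels are assigned to the nearest peak; clusters below
`min_cluster_support` pixels or spanning two or more nominal row spacings
are dropped (the spanning rule is stated as "split or dropped" in principle;
this implementation drops, because splitting a merged density plateau has no
well-defined split point). Adjacent peaks without a sufficiently deep valley
between them — the valley must dip below `valley_frac = 0.85` of the smaller
peak — are merged, which collapses a closed canopy into a single wide mode.
Detection is rejected outright (empty result) when fewer than `min_rows`
clusters survive or when the fitted inter-row spacing deviates more than 50%
from the nominal spacing; both signal that row-based extraction is
unreliable on that date. Row counts are capped at `max_rows` (the rows
visible in the image, typically the plot's rows plus one neighbour row on
each side), keeping the clusters nearest the image centre. For dense
nine-row plots whose rows cannot be separated, `single_row = TRUE` treats
the whole green mass as one cluster.

**3. Row alignment** (`fit_row_lines()`, `align_rows()`). Each cluster's
pixels are reduced to one median y per image column, and a line is fitted
with Theil–Sen (deterministic, resistant to well over 20% outlying columns;
Huber M-estimation is available). One rigid rotation — `atan` of the
support-weighted mean of per-row slopes — is removed about the middle row's
midpoint. A weighted mean rather than the weighted median is used across
rows: each per-row fit is already robust, and averaging the (independent)
per-row slope errors improves angular precision by roughly the square root
of the row count, which matters for the ±0.3° recovery target. Because
nearest-peak assignment slightly truncates a slanted row's extreme
y-values, one pass attenuates the angle by a few percent; `align_rows()`
therefore iterates (up to 3 passes, each rotating the *original* mask by
the accumulated angle so resampling error does not compound) until the
residual slope is below 0.02°. This also makes alignment idempotent to
within 0.05°.

**4. Plot boundary and CC** (`derive_plot_boundary()`,
`compute_canopy_cover()`, `propagate_boundary()`). With several rows, the
upper and lower bounds are the median y of the outer retained rows. Taken
literally, outer-row centrelines exclude the outer half of each outer row;
the default therefore expands the bounds by half a row spacing
(`expand_half_spacing = TRUE`), and a strict-centreline mode is kept for
compatibility with archives that used the literal rule. With a single
cluster, bounds are the cluster centre ± 1.5 IQR of its y-distribution
(computed over the cluster's own pixels — the natural reading when only one
cluster exists). X bounds default to the full width, optionally inset by
`x_margin_frac`. CC is the green fraction of the rectangle, with inclusive
integer pixel bounds (area `= (y_bottom - y_top + 1) * (x_right - x_left +
1)`), making counts bit-reproducible. Once the canopy closes and rows
vanish, the boundary is propagated: the per-coordinate median over all
earlier successfully detected geometries of the same plot.

**5. Merging** (`merge_datasets()`). Row-based records are preferred
whenever at least `min_rows` rows were detected; otherwise the
total-fraction record with the propagated boundary fills in. How the
original archive reconciled overlapping dates is not documented; this
precedence rule is the package's own choice and is recorded per record in
the `method` and `provenance` columns.

## The statistical layer

**Spatial adjustment and BLUEs** (`fit_blues()`). Plot values are modelled
as `value ~ genotype + f(range, row)` with genotype fixed and `f` a
tensor-product penalized spline (`mgcv::te`, 5×5 marginal basis by default,
REML smoothing). This replaces the PSANOVA decomposition used by dedicated
field-trial software with a single smooth surface of equivalent purpose;
parameter recovery, not equivalence to any specific package, is the
validation criterion. The smooth is centred, so genotype BLUEs are
`intercept + genotype effect` with standard errors from the model
covariance; with the spatial term off, this reduces to ordinary least
squares and BLUEs equal genotype means exactly on balanced data. The basis
is shrunk automatically (with a warning) when the trial is too small to
support it.

**Outlier rule** (`remove_outliers()`). Plots whose residual exceeds 3
times the residual standard deviation (the descriptive SD of the residual
vector) are removed and the model refitted once — a single pass, not
iterated.

**Heritability** (`estimate_heritability()`). Genotype becomes a random
effect (`lme4`, REML) and the entry-mean broad-sense heritability is
`H2 = s2g / (s2g + s2e / r)` with `r` the mean replication. Generalized
heritability definitions exist and differ when designs are unbalanced; the
entry-mean form is used because it has a closed form under the simulator's
assumptions, giving an exact recovery target (`H2 = 0.75` at
`s2g = s2e = 1, r = 3`). Dates with `H2 < 0.2` carry little genotypic
information and are dropped by `filter_low_heritability()` before curve
fitting.

**Growth curves and timing** (`fit_gam()`, `extract_crossing_dates()`).
Per-genotype CC trajectories are fitted with a penalized regression spline
of numeric date, `k = 10` basis functions, smoothing parameter by GCV
(REML optional). The fitted curve is evaluated on a 0.1-day grid —
interpolation error far below the biological signal — the maximum located,
and 50% crossings found by linear interpolation: the last upward crossing
before the maximum is canopy closure, the first downward crossing after it
is senescence timing. Curves that never reach the level, or senescence too
delayed to be observed within the season, yield `NA` rather than an error.
CC values are modelled untransformed (no logit), matching how the raw
fractions are reported.

**Auxiliary traits.** Plot height from a laser-scan profile is the 97th
percentile (linear order-statistic interpolation, `height_percentile()`);
trait relations use plain Pearson correlation with pairwise-complete
observations (`correlate_traits()`); shortwave radiation converts to PPFR
by the fixed factor 2.04 (`radiation_to_ppfr()`).

## The synthetic field: what it emulates, and what it does not

Because the pipeline's accuracy can only be judged against known truth, the
package ships a renderer (`render_plot_image()`, `render_season()`) that
draws soil-background scenes with 1-9 plant rows as jittered overlapping
disks, rigid scene rotation (±15°), emergence gaps, off-row weed blobs,
per-pixel colour noise, and a greenness scalar that fades plants from green
to a senesced brown. Ground truth is exact: the true green-pixel set, row
centres, rotation, and the true CC as an exhaustive pixel count inside the
true boundary. The true boundary uses the same convention as the detector's
default (outer-row centrelines expanded by half a spacing, x inset by
`x_margin_frac = 0.1` so the rectangle stays inside rendered content under
rotation) — the comparison is then apples-to-apples. Within-row plant
jitter is SD `plant_radius/4`; at the default geometry this leaves the
realized row orientation within about 0.1° of the nominal rotation, which
is what makes the ±0.3° recovery check meaningful.

The renderer deliberately omits radiometric realism: no shadows, no
specular leaves, no perspective beyond the rigid rotation, no mosaicking of
neighbouring plots, and 8-bit PNG rather than camera raw (raw development
is I/O, not method). Passing tests on rendered scenes therefore validates
the *geometry* of the pipeline — clustering, alignment, boundary logic,
counting — and the calibration of its statistics, not robustness to field
illumination, which only real archives can test.

`simulate_trial()` generates the statistical counterpart: a randomized
complete block layout (blocks as contiguous column bands, genotypes
randomized within block), per-genotype double-logistic CC curves, an
additive genotype effect `a_i ~ N(0, s2g)`, a smooth zero-mean fertility
gradient (half a sine/cosine cycle across the field — the scale of trend a
spatial model should absorb), and i.i.d. residual noise. Values are clipped
to [0, 1] on the CC scale by default; variance-component studies use
`clip = FALSE`, since clipping at the stated unit variances would destroy
the closed-form heritability. `simulate_weather()` produces hourly records
with diurnal and seasonal cycles, daylight-only radiation and PPFR derived
by the standard factor.

## Problem sizes used in validation

The test suite validates at these scales, chosen to mirror the trials the
method is meant for while staying computable in minutes: 360×480-px scenes
(200-scene sweeps for CC recovery across rotation ±5°, gap rate 0-0.4,
weed rate 0-3; 100-scene sweeps for rotation and row-count checks);
36-genotype trials with 3 replicates for heritability recovery (200
replicate trials) and with 8 replicates — the most replicated season layout
— for BLUE coverage (200 trials); 12 genotypes × 6 replicates, the typical
replication of check varieties, for the outlier-rule check. The BLUE check
uses the larger layout deliberately: "within 2 SE" has only ~0.45
percentage points of nominal margin over a 95% target, so small-sample
t-dispersion and smoothing-parameter variability must be kept negligible
for the check to reflect calibration rather than sample size.

## Known limitations

* Colour-ratio segmentation has no illumination or shadow model; thresholds
  must be re-tuned per camera/site.
* Row detection assumes approximately horizontal rows after a single rigid
  rotation; it does not model row curvature or strong perspective.
* Boundary propagation assumes the plot does not move between dates beyond
  what the median over history absorbs.
* The spatial model is a generic tensor-product smooth; designs with strong
  row/column artefacts (serpentine harvest effects, drill misses) may need
  the dedicated field-trial decompositions it stands in for.
* Entry-mean heritability is one of several definitions; unbalanced designs
  make the choice material.
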