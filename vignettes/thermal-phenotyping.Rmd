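---
title: "Retrieving plant temperature and stress indices from UAV imagery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Retrieving plant temperature and stress indices from UAV imagery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermopheno)
```

## The problem

Salinity stress makes plants close their stomata; reduced transpiration
means reduced evaporative cooling, so a stressed canopy runs warmer than an
unstressed one. A thermal camera on a low-flying UAV can therefore screen
hundreds of plants per flight for stress — provided the surface temperature
of *vegetation* can be isolated from a much hotter soil background, from
white field tags, from mixed canopy/soil edge pixels, and from the additive
drift of uncooled microbolometer sensors. `thermopheno` implements that
retrieval chain and converts the retrieved plant temperature
$T_p$ into stress indicators, for trials where individual plants have
already been delineated from co-registered RGB imagery.

The package's defaults emulate a four-plot tomato salinity trial: two
freshwater control plots and two plots irrigated with increasingly saline
water, 15 × 20 plants each (1,200 in total), imaged five times across a
growing season at a 0.015 m thermal and 0.005 m RGB ground sample distance.

## The model

**Thermal stress signal.** For each plant, $dT_p = T_p - T_a$, the
deviation of the mean vegetation-pixel temperature from the flight-mean air
temperature. Transpiring canopies sit near or below $T_a$; stressed ones
rise above it.

**Crop water stress index.** To compare flights with different weather,
$dT_p$ is positioned between a fully transpiring lower limit and a
non-transpiring upper limit:

$$\mathrm{CWSI} = \frac{dT_p - dT_{LL}}{dT_{UL} - dT_{LL}}$$

The index is deliberately not clipped: values below 0 flag canopies cooler
than the lower baseline, values above 1 canopies hotter than the
non-transpiring ceiling. Three baseline schemes are implemented:

* **Statistical** (`statistical_baselines()`, always available): the lower
  limit is the mean of the coolest 5% of retained control-plot plants
  (count $m = \lceil 0.05\,n\rceil$, so it is never empty), expressed as a
  deviation from $T_a$; the upper limit is $T_a + 9\,°C$. Only air
  temperature is needed beyond the imagery, but the scene must contain both
  stressed and unstressed plants.
* **Empirical** (`empirical_lower_limit()`): the classic non-water-stressed
  baseline $dT_{LL} = a + b\cdot\mathrm{VPD}$. The crop-specific intercept
  and slope must be supplied by the user — they come from season-long
  observations of unstressed plants and no defaults are bundled; runs
  without them simply disable this scheme with a logged notice.
* **Theoretical** (`theoretical_lower_limit()`): the energy-balance form
  $dT_{LL} = \frac{r_a R_n}{C}\frac{\gamma}{\Delta+\gamma} -
  \frac{\mathrm{VPD}}{\Delta+\gamma}$. The matching theoretical upper limit
  requires the aerodynamic resistance of a non-transpiring canopy and is
  notoriously error-prone, so the pipeline pairs this lower limit with the
  same $T_a + 9$ ceiling; the run manifest flags the expression as the
  package's documented form of the energy-balance baseline.

**Vapor pressure deficit.** `saturation_vapor_pressure()` uses the
Tetens form with FAO-56 constants,
$e_s = 0.6108\exp(17.27\,T_a/(T_a+237.3))$ kPa, and
$\mathrm{VPD} = e_s(T_a)(1 - RH/100)$. Recomputing VPD from the shipped
flight-weather table reproduces the recorded flight VPDs to within
0.008 kPa, which is why this particular $e_s$ form was adopted. A flight is
summarized by one consistent triple: mean $T_a$ and mean $RH$ over the
half-open window $[\mathrm{start}, \mathrm{start}+\mathrm{duration})$, with
VPD recomputed from those means rather than averaged per minute.

## The retrieval chain

1. **Calibration** (`apply_ambient_calibration()`): raw counts are mapped
   through a supplied per-pixel linear model
   $T = c_0 + c_1\,\mathrm{raw} + c_2\,\bar T_a$, which absorbs vignetting
   and the sensor's ambient-temperature dependence. The coefficients are
   inputs; deriving them is a laboratory exercise outside this package.
2. **Within-swath averaging** (`average_swath_overlap()`): consecutive
   frames of a flight line overlap by roughly 93% and are acquired
   near-simultaneously, so every mosaic pixel is the arithmetic mean of all
   covering frames, suppressing frame noise.
3. **Between-swath normalization** (`chain_normalize_swaths()`): adjacent
   flight lines are minutes apart and an uncooled sensor drifts on that
   time scale. Assuming a true 0 °C difference in the ~60% sidelap, each
   strip is shifted by the mean (optionally median) overlap difference with
   its already-corrected predecessor. The first swath anchors the chain, so
   offsets are identifiable only relative to it; the simulator injects
   drift with the first swath fixed at 0 for the same reason. The
   correction is additive only — the physics is a temperature offset, not a
   gain change.
4. **Assembly** (`assemble_mosaic()`): non-overlap pixels are copied,
   sidelap pixels averaged, uncovered pixels stay nodata.
5. **Resampling** (`resample_nearest()`): the RGB orthomosaic is brought
   onto the thermal grid by nearest pixel center, so thermal and
   reflectance values can be indexed jointly. Grids use a pixel-center
   georeference convention with row 1 at the northern edge.
6. **Masking** (`vegetation_mask()` and friends), per delineated plant:
   * white tags: pixels with blue reflectance strictly above the
     *per-plant* 99.5th percentile (type-7 interpolated order statistic)
     are dropped. The percentile is per plant because tags are attached to
     individual plants and per-plant statistics are insensitive to
     brightness differences between plants.
   * vegetation: GRVI $=(\mathrm{green}-\mathrm{red})/(\mathrm{green}+
     \mathrm{red})$ strictly greater than the threshold. The fixed
     threshold 0 is the default because it is comparable across flight
     dates; a scene-adaptive 2-means threshold
     (`kmeans_grvi_threshold()`) is available and can legitimately go
     negative on scenes with much senesced material.
   * temperature ceiling: positive-GRVI pixels strictly warmer than
     $T_a + 9\,°C$ are relabeled `overtemp` — they are mixed soil/canopy
     pixels or misclassifications. A pixel at exactly $T_a+9$ is retained
     ("warmer than" is strict). Applying the ceiling can only trim the
     upper tail, so it never inflates a plant's temperature spread.
   * sunlit/shaded (`sunlit_shaded_split()`): 5-means on blue reflectance;
     the cluster with the lowest center is the shaded pool and its maximum
     blue value the sunlit threshold. The cluster count can be checked with
     `elbow_optimal_k()`.
7. **Retrieval** (`zonal_stats()`, `retention_filter()`): per-plant min,
   max, mean, median, standard deviation and pixel count over surviving
   vegetation pixels. A plant keeping fewer than 10% of its delineated
   pixels is treated as dead or too sparse and dropped; exactly 10% passes.
8. **Cohorts** (`compare_treatments()` etc.): pooled-variance two-sample
   t-tests at $\alpha = 0.01$ per index (Welch by flag), control-anchored
   percentage differences, the share of plants with CWSI strictly above
   0.35, and the early-detection contrast of median CWSI between plants
   that later died and plants that stayed healthy.

## Numerical choices

* 1-D 2-means has an exact solution — optimal clusters are contiguous in
  sorted order — implemented in `kmeans_1d_exact()` by prefix-sum scan of
  all splits. The default clustering path is iterative
  (`stats::kmeans`, Hartigan–Wong, 10 restarts, 300 iterations) and is
  tested against the exact solver; the decision boundary is the midpoint
  between the highest low-cluster and lowest high-cluster value.
* `elbow_optimal_k()` maximizes the second difference of *log*-inertia.
  On the raw scale the roughly geometric decay of the k-means objective
  puts the sharpest bend at $k=2$ regardless of structure; the log scale is
  unit-invariant and recovers the true mode count on separated mixtures.
* Per-plant standard deviation is population-form ($\div n$), the common
  zonal-statistics default; sample-form is a switch.
* Ties and boundaries are all resolved explicitly: GRVI must *exceed* the
  threshold, the ceiling removes only *strictly* warmer pixels, retention
  keeps exactly 10%, the stress-proportion cut is strict.
* Grids are plain matrices with a pixel-center georeference; rasters are
  written as 32-bit TIFF with an affine value encoding and a JSON sidecar
  (scale, offset, nodata, georeference), which round-trips values to about
  1e-6 relative precision.
* Plants whose delineation is entirely nodata in the thermal mosaic are
  reported as not retained with reason `nodata` rather than `sparse`.

## What the simulator emulates — and what it does not

`generate_scene()` renders the trial geometry (four plots, 1,200 plant
discs with a one-pixel mixed boundary ring), treatment-dependent canopy
temperature (control $dT_p \sim N(2.5, 1.0)$ °C, salt $N(4.2, 1.2)$ °C —
inside the ranges such trials report mid-season), hot soil (+18 °C over
$T_a$, so mixed pixels are unmistakably warm), sunlit/shaded pixels
(±0.4 °C, blue reflectance 0.12 vs 0.05), white tags (high blue, about
+5 °C), per-arm senescence (2% control, 8% salt; brown and hot, so both the
GRVI and ceiling rules catch them), "declining" plants that are still green
but run 1.5 °C hotter (3% control, 10% salt; the early-detection cohort),
sensor noise (reflectance sd 0.02, thermal sd 0.3 °C) and per-swath drift
(sd 1 °C, first swath anchored). The mixed edge ring blends soil at weight
0.6, which keeps every edge pixel above the $T_a+9$ ceiling for any
plausible $dT_p$ — that is the failure mode the ceiling exists to fix, made
exactly removable.

Plant spacing is compacted (0.30 m) relative to a production field so the
full trial renders on a desk-scale raster (320 × 1,680 thermal pixels);
all class contrasts and the plant/pixel counts per plant are preserved.
Deliberately *not* modeled: radiative transfer, diurnal temperature
dynamics, wind-driven canopy movement, emissivity variation, spatial
autocorrelation of soil moisture, and geometric distortion — so passing the
synthetic suite demonstrates the *computational* correctness of the chain
(masking, drift correction, statistics), not robustness to every optical
effect in real imagery.

Test and validation problem sizes are chosen to keep the default suite
fast: unit tests use a 60-plant layout, mask-fidelity checks a 240-plant
layout, and the cohort-recovery and arm-mean checks the full 1,200-plant
trial; drift-recovery flights use 17 swaths of 12 frames.

## A worked run

```{r, eval = FALSE}
res <- run_end_to_end(list(simulate = TRUE, out_dir = "run1", seed = 42))
res$comparisons      # t-tests for dTp and CWSI per treatment
res$proportions      # share of plants with CWSI_S > 0.35 per arm
res$baselines$statistical
```

On the default simulated trial this reports a salt-minus-control $dT_p$
difference of about 1.7 °C (significant at $\alpha = 0.01$), mean
CWSI$_S$ near 0.20 (control) versus 0.41 (salt), and roughly 11% of
control against 64% of salt plants above the 0.35 stress threshold —
the qualitative picture a successful salinity screen should show.

## Known limitations

* The statistical baseline assumes both stressed and unstressed plants are
  present; a uniformly stressed scene would push the lower limit up and
  compress the index.
* The chain normalization equalizes *means* in the sidelap; a true
  cross-swath temperature gradient (e.g. a wind change mid-flight) would be
  absorbed into the correction.
* The theoretical upper limit is intentionally not derived; the $T_a+9$
  ceiling doubles as the non-transpiring limit, which couples the masking
  rule and the index scale.
* Empirical baseline coefficients are user inputs; results under that
  scheme are only as good as the supplied regression.
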