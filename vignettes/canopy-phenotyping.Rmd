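---
title: "Canopy trait extraction from field RGB-D and thermal imagery: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Canopy trait extraction from field RGB-D and thermal imagery: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canopytraits)
```

`canopytraits` implements the data-processing side of a ground-based
high-throughput phenotyping rig for row crops grown in a single-plant
layout (SPL): one plant per 1.52 m x 1.52 m plot, imaged from nadir by an
RGB-D pair and a thermal camera about 2.4 m above ground while the vehicle
drives the rows. This vignette describes the models and procedures, the
parameters that matter, the synthetic scene generator used for testing, the
numerical choices, and the known limitations.

## From frames to plants

Every frame carries a GPS record of the image centre, and every plant a
surveyed main-stem position. `assign_images()` assigns, per plant and per
sensor, the frame minimising the Euclidean distance between the two
positions. The distance computation is planar: `lonlat_to_local()` projects
longitude/latitude equirectangularly about the field centroid, which at
field scale (tens of metres) distorts distances by well under a centimetre.
Ties between equidistant frames are broken by earliest timestamp, then
lexicographic frame id, so assignment is a pure function of its inputs and
invariant to row order. Frames spanning two adjacent plants are not given
any special treatment beyond minimum distance; in an SPL field with the
rig's fields of view, a frame centred on a plant covers little of its
neighbours.

Air temperature at a frame's timestamp comes from the 1 Hz auxiliary
environment log by nearest-record lookup (`air_temperature_at()`). With one
record per second, interpolation would change the result by at most the
within-second temperature change, so it is not used; queries falling more
than 60 s outside the log are flagged as extrapolated rather than refused.

## Morphological traits from depth + color

`reconstruct_point_cloud()` inverts the pinhole model per pixel: for a
0-based pixel $(u, v)$ with raw depth $d > 0$ (in raster units of
`depth_scale` metres, 1 mm by default),

$$x = \frac{(u - c_x)\, d s}{f_x}, \quad
  y = \frac{(v - c_y)\, d s}{f_y}, \quad
  z = h_{cam} - d s,$$

with the ground plane at $z = 0$ established from the mounted camera
height. x is across-row, y in-row, z up; zero-depth pixels (no return) are
dropped. Depth and color are assumed co-registered on a common grid, as
delivered by consumer RGB-D SDKs.

Vegetation is separated from soil by the excess-green index on
chromaticity-normalised channels, $ExG = 2g' - r' - b'$ with
$r' = r/(r+g+b)$ etc.; `segment_canopy()` keeps points with $ExG > 0.15$.
The classic chromaticity normalisation is used because it makes the index
illumination-invariant; black pixels score 0 and fall to background.

From the segmented cloud, `morphological_traits()` computes:

* **H** (plant height): the largest $z$;
* **WAR/WIR** (widths across/in row): the $x$ and $y$ extents;
* **PLA** (projected leaf area): the area covered by the canopy boundary in
  the ground-plane projection. The default boundary is the 2D convex hull
  (deterministic, order-free, with an exact shoelace area); an
  occupancy-grid mode (default 5 mm cells) is provided for strongly concave
  canopies, where a hull overestimates;
* **CV** (canopy volume): the volume of the 3D convex hull, computed by an
  incremental hull construction written for this package (no installed
  package provides 3D hulls here). Facet orientation is fixed against an
  interior point, and the volume is the sum of signed tetrahedra.

Degenerate inputs are results, not errors: fewer than 3 non-collinear
points give PLA = 0, fewer than 4 non-coplanar points give CV = 0, both
flagged. Growth rates between measurement days are simple difference
quotients per day and may legitimately be negative.

An optional statistical outlier filter (`filter_outliers()`, k-nearest
mean-distance rule) is provided but **off by default**: whether any outlier
removal should precede trait extraction is a judgement call, and the traits
above are already robust to isolated ground noise through the ExG filter.

## Canopy temperature from thermal frames

A transpiring canopy at midday is cooler than sunlit soil, so
`segment_thermal()` runs Otsu's method on a 256-bin histogram spanning the
frame's min-max range and takes the **cold** class as plant (a flag covers
the opposite polarity, e.g. for cold soils). The threshold is the bin
boundary maximising the between-class variance $w_0 w_1 (\mu_0 - \mu_1)^2$;
ties take the lowest boundary. A constant frame is a degenerate-histogram
error.

The binary mask is labelled 8-connected (`find_components()`), and each
component gets its area-weighted centroid and the exact minimum enclosing
circle of its pixel centres (a Welzl-style construction restricted to the
component's convex-hull pixels). The component closest to the image centre
is the target plant; any component whose circumcircle is **disjoint** from
the target's,

$$(r_i + r_c) \le \sqrt{(x_i - x_c)^2 + (y_i - y_c)^2},$$

is classified as a neighbouring plant or weed and removed; intersecting
components stay in the final mask. The $r$ values are treated as radii:
that is the reading under which the inequality is the standard
disjoint-circles test, and the package keeps the raw separate/kept flags on
the output so the opposite convention remains recoverable. Mean canopy
temperature is the arithmetic mean of the *original* frame over the final
mask, and the reported trait is Tc - Ta against the concurrent air
temperature.

For the calibration-time repeatability analysis, `compensate_series()`
removes ambient drift from a paired camera/thermocouple series as
`ti_comp = ti_raw + (tc_ref - tc)`. The reference `tc_ref` defaults to the
grand mean of the thermocouple series, with the first frame's reading as an
alternative; either choice cancels the shared drift term exactly, and the
grand mean keeps the compensated series on the scale of the measured
temperatures. `paired_difference_summary()` gives the mean and sample SD of
shaded-minus-unshaded canopy temperatures used to rule out a shading effect
of the rig's enclosure.

## Calibration computations

* `fit_spectral_axis()`: least-squares polynomial from spectral pixel index
  to wavelength. The default degree is 1 — on this class of spectrograph
  the axis is nearly linear (adjusted R-squared indistinguishable from 1) —
  with degrees 2-3 available. The fit is refused if its RMSE exceeds the
  spectrograph's nominal resolution (2.7 nm default) or if the fitted axis
  is not strictly increasing.
* `spatial_resolution()`: target length over pixel count, reported at one
  decimal as such targets conventionally are (full precision kept as an
  attribute).
* `resolvable()`: a pattern of $r$ line pairs/mm needs two pixels per pair,
  so the limit is $1/(2r)$ mm/pixel, inclusive at the boundary.
* `validation_regression()`: OLS of device against reference with adjusted
  R-squared and two RMSE summaries — residual RMS about the fit (primary)
  and RMS deviation from the identity line — because accuracy reports in
  this field do not always distinguish the two.
* `data_budget()`: per-stream frame size x frame rate and designed/maximum
  totals, at one decimal. Frame sizes are taken as supplied rather than
  recomputed from pixel dimensions, so the budget reflects the stream
  format actually written.

## Genetics statistics

Pearson correlations between traits (or growth rates) and fiber yield use
the t-distribution p-value on $n-2$ df, with the conventional star coding
at 0.05/0.01/0.001; an exact permutation option exists for very small n.
Genotype differences use one-way ANOVA plus pairwise Tukey-Kramer
comparisons (studentized range on the error mean square, valid for unequal
group sizes), summarised as a compact letter display via insert-absorb with
groups sorted by descending mean.

Broad-sense heritability is
$$H^2 = \frac{V_G}{V_G + V_E},$$
and the package's default convention takes $V_G$ and $V_E$ **directly as
the genotype and error mean squares** of a per-date genotype ANOVA, as
field-phenotyping reports commonly do. This is deliberate fidelity to that
practice rather than to the textbook variance-component estimator
$V_G = (MS_G - MS_E)/n_0$, which is available as
`method = "variance_components"`. The two differ predictably: with $r$
replicates per genotype, $E[MS_G] = r V_G + V_E$, so the mean-squares
convention yields approximately $(r V_G + V_E)/(r V_G + 2 V_E)$ — higher
than the plot-level $V_G/(V_G+V_E)$ whenever $r > 1$. The tests verify the
estimator against exactly this analytic expectation.

`heritability_pipeline()` applies an exclusion rule first: by default,
genotypes that are the sole member of their species group are dropped (a
single outgroup cultivar would otherwise inflate the apparent genotype
variance), then one ANOVA per date is run over the remaining genotypes.
With one plant per plot, error degrees of freedom come from having several
plants of each genotype across the field; the pipeline errors informatively
when the replicate structure leaves no error df.

## The synthetic field generator

`sim_config()`/`generate_field()`/`render_scene()` produce a complete
synthetic data set whose defaults are the study conditions the package is
designed for: a 12 x 11 grid at 1.52 m pitch (132 plants), 23 genotypes in
three groups with a single-genotype outgroup, measurement dates at DAP
51/65/72/87/94, cameras 2.4 m above ground, canopies 8 degC cooler than
soil with 0.3 degC per-pixel thermal noise, 1 mm depth quantisation with
2 mm depth noise, and genotype/plant variance components of 0.006/0.004 m^2
on the canopy semi-axes (ratio 0.6).

The canopy is the upper half of an ellipsoid with semi-axes $(a, b, c)$,
chosen so every true trait is closed-form: $H = c$, $WAR = 2a$, $WIR = 2b$,
$PLA = \pi a b$, $CV = \tfrac{2}{3}\pi a b c$. Genotype effects are shared
across a genotype's plants and constant across dates, so per-plant height
is monotone through canopy development as real canopies are. Latent fiber
yield is linear in PLA at DAP 87 plus noise — a device for producing
realistic correlation magnitudes, with no claim of biological realism.
Scenes are ray-cast: each pixel ray is intersected with the half-ellipsoid
analytically; canopy pixels are painted green (ExG well above threshold)
and soil brown (ExG about 0); thermal frames optionally include fragments
of the two in-row neighbours at the frame margins to exercise the
circumcircle filter. Everything is deterministic given the config seed
(per-frame render seeds are derived from it).

Default raster sizes are 128 x 106 (depth/color) and 160 x 120 (thermal) —
quarter-scale versions of the reference sensors with the same fields of
view. At 2.4 m this gives ~26 mm depth-pixel footprints, which is coarse
but sufficient: the apex of a smooth canopy is sampled to within about a
millimetre, so height recovery is limited by depth quantisation and noise,
not raster size. The test and acceptance runs use 50 rendered plants and
200 replicate trait-only fields; these sizes give stable estimates
(height-RMSE SE well under the 0.035 m criterion; heritability-mean SE
about 0.002) while keeping a full run to tens of seconds.

### What the generator does and does not emulate

It emulates: the SPL geometry and frame-to-plant assignment problem, pinhole
depth imaging with quantisation and noise, color-based vegetation
segmentation, canopy-cooler-than-soil thermal contrast with neighbour
contamination, diurnal air-temperature drift, genotype/environment variance
structure, and a yield-morphology correlation.

It does not emulate: leafy (non-convex, porous) canopy geometry, occlusion
between organs, specular or shadow artefacts in color, emissivity and
atmospheric effects in thermal (the real camera handles these internally),
GPS multipath, or wind-induced motion blur. Consequently, passing recovery
tests shows the *pipeline arithmetic* is right at sensor-accuracy scales;
it does not certify accuracy on real, porous canopies, where self-occlusion
biases widths, PLA and CV downward. That bias is visible even in the
synthetic scenes: a nadir camera only sees the canopy cap above the tangent
line, so extracted WAR/WIR/PLA/CV run below the closed-form truth while H
and Tc are recovered essentially exactly — the same qualitative behaviour
expected in the field.

## Numerical choices

* Hull tolerance: $10^{-12}$ of the coordinate scale for facet visibility;
  degenerate (coplanar) inputs are detected and return 0 rather than a
  near-zero noise value.
* Minimum enclosing circle: computed on the component's convex-hull pixels
  only (the optimum is determined by at most three hull points), with a
  relative containment tolerance of $10^{-10}$.
* Otsu binning: 256 equal bins over the frame's min-max range; candidate
  thresholds are interior bin boundaries; ties take the lowest.
* Component selection ties: larger pixel count, then lower label index.
* ANOVA on exactly constant data: both mean squares are clamped to zero and
  F is reported as undefined rather than 0/0.
* Depth rasters are 16-bit (mm); thermal rasters are stored as 32-bit float
  TIFF under a fixed affine encoding over (-40, 150) degC because the TIFF
  writer stores samples in [0, 1]; the round-trip error is ~1e-6 degC.

## Known limitations

* PLA's convex-hull boundary overestimates strongly concave canopies; use
  the grid mode there.
* CV requires a reasonably dense cloud; sparse clouds underestimate volume.
* The mean-squares heritability convention is not an unbiased estimate of
  plot-level $V_G/(V_G+V_E)$; use the variance-components option when that
  is the target quantity.
* The thermal plant/soil polarity assumption (plant = cold) fails for
  canopies warmer than background (e.g. overcast, wet soil); the polarity
  flag must then be set explicitly.
* No organ-level segmentation, flower/boll detection, or hyperspectral
  trait extraction is attempted.
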