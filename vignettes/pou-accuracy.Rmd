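---
title: "Survey geometry, POU and measurement accuracy for SfM phenotyping clouds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Survey geometry, POU and measurement accuracy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenopou)
```

## The problem

A gantry-mounted camera sweeps over a greenhouse bed in parallel routes,
taking nadir snapshots that a structure-from-motion (SfM) pipeline turns
into a dense, colored 3D point cloud.  Plant dimensions (height, canopy
extent) are then measured from the cloud.  Reconstruction quality — and
hence measurement accuracy — is governed by three acquisition knobs:
side overlap $O_x$ between neighboring routes, forward overlap $O_y$
along a route, and spatial resolution $SR$ in pixel·mm⁻¹.

`phenopou` models this with the standard survey relations.  With sensor
size $S_w \times S_h$ (mm), focal length $F_R$ and lens height $H$, the
ground footprint is

$$FOVW = S_w H / F_R, \qquad FOVH = S_h H / F_R,$$

and with route spacing $L_x$ and forward step $L_y = v\, t_I$ (belt
speed times snapshot interval)

$$O_x = \frac{FOVW - L_x}{FOVW}\,100\%,\qquad
  O_y = \frac{FOVH - L_y}{FOVH}\,100\%,\qquad
  SR = \frac{imW}{FOVW}.$$

The *power of unit* collapses the three into one scalar,

$$POU = \frac{SR \cdot 10^4}{(100 - O_x)(100 - O_y)}
  \quad \text{(pixel·mm}^{-1}\text{)},$$

interpretable as the density of shared pixel information per unit of
ground area.  Higher POU means denser, more complete clouds; the
interesting empirical fact is that planimetric (x/y) measurement error
grows as a *power law* in falling POU while height error stays nearly
flat, so POU directly prices accuracy against acquisition and
processing cost.

```{r}
cam <- camera_config()   # 6.17 x 4.55 mm sensor, 4 mm lens, 1200 mm high
compute_fov(cam)
compute_pou(2.78, 90, 95)
head(design_pou_grid(), 4)
```

### Numerical conventions in the geometry module

All computations keep full precision; only reporting rounds overlaps and
POU to integers and SR to two decimals, which is the precision survey
design tables are printed at.  One subtlety: the conventional integer
POU values (556, 278, …) are quoted from the *two-decimal* SR.  The
exact ratio $5152/1851 = 2.7834$ would give 557 where the table says
556.  `compute_pou` is exact; `design_pou_grid()` and `plan_grid()`
expose the table-convention integers in `pou_int`.  The snapshot
interval defaults to the design value 3.0 s (which makes the
22.75/68.25/113.75 mm·s⁻¹ belt speeds land exactly on 95/85/75 %
forward overlap); a measured interval such as 3.2 s can be configured
instead.  An overlap of exactly 100 % is rejected rather than yielding
an infinite POU.  The design grid's second resolution block is the
half-scale downscale, SR 1.39 pixel·mm⁻¹ — downscaling is modelled as
dividing the pixel dimensions, never as image resampling.

## Measuring calibration objects

Accuracy is probed with foam calibration objects — cuboids, cylinders
and mushrooms (hemispherical cap on a cylindrical stem) — whose true
dimensions are known from caliper measurements.  The per-object pipeline
(`measure_object`) is:

1. **Rectangle segmentation** (`crop_rectangle`): closed-bound x/y crop
   of one object out of the scene.
2. **Bottom zeroing** (`zero_bottom`): $Z_{bottom}$ is the 1st
   percentile of z, not the minimum, so sparse under-floor noise cannot
   drag the floor down; it is subtracted from every z.
3. **Height** (`measure_height`): the trimmed-histogram mean of z over a
   central patch of the object top ($Z_{top}$; equal to the height after
   zeroing).
4. **x/y dimensions** (`slice_extents`, `measure_xy`): z is quantized
   into 1 mm slices ("the points with the same Z" — continuous z never
   repeats exactly); each slice contributes its extreme-point extents
   $X_{max}-X_{min}$ and $Y_{max}-Y_{min}$; the per-slice extents are
   then reduced by the same trimmed-histogram mean (a max-over-retained
   reduction is available via `reduction = "max_retained"`; the mean is
   the default because it matches the height estimator — the original
   procedure does not state its reduction).

### The trimmed histogram, and why it has a mass cap

The noise-removal rule bins a sample into 20 equal-width bins over its
range and discards the values in the 5 lowest-edge and 5 highest-edge
bins.  Read literally, this rule destroys the estimate whenever noise is
one-sided: with the bulk at 150 mm and a few outliers at 200 mm, the
bulk itself occupies the lowest bin and would be discarded.  Since the
rule's purpose is to shed *extreme points and noise*, not the signal,
`trimmed_histogram_mean` drops bins from the outside in and stops a side
early if dropping the next bin would discard more than 30 % of the
sample from that side (`max_trim_frac`).  For mid-range bulks — the
intended regime — this is identical to the literal rule (a uniform
sample loses exactly 25 % per side); under one-sided outliers it keeps
the bulk and still sheds the tail.  Degenerate inputs (a constant
sample, or a trim that would empty the sample) fall back to the plain
mean.  Bin assignment is right-closed at the top: a value equal to the
maximum falls in the top bin.

```{r}
trimmed_histogram_mean(seq(0.5, 19.5, 1))          # uniform: exact 25%/side
trimmed_histogram_mean(c(150 + runif(100, -.5, .5), rep(200, 3)))
```

### Automating the manual center selection

In the original workflow an operator draws a small rectangle on the
center of each object's top.  `measure_height` automates this as: take
the *top slab* of the cloud (z within the top 5 % of the robust range
between the 5th and 95th z percentiles), form its footprint bounding
box, and keep the central 30 % per axis.  Two deliberate deviations from
the obvious "central half of the whole footprint":

* the footprint is that of the top slab, because the whole-cloud
  footprint includes the surrounding bed — a central *half* of it would
  capture the lateral walls of a cuboid and average wall z into the
  height (halving the estimate);
* the fraction is 0.3, not 0.5, because on a hemispherical cap the
  selected patch has mean height $\approx r - \rho^2/(4r)$ below the
  apex for patch radius $\rho$; 0.3 keeps this curvature bias below the
  1 mm slice width for the default cap ($r = 60$ mm) while a flat top is
  measured exactly regardless.

On noise-free generator clouds the pipeline recovers cuboid and cylinder
dimensions to well under 1 mm in all three axes.  The mushroom's x/y is
biased low by construction: hemisphere slices shrink toward the apex and
only the lower tail of the extent histogram is trimmed, so the trimmed
mean under-reads the equatorial diameter.  This mirrors the empirical
finding that the mushroom shape has the largest planimetric errors; the
bias is documented rather than patched, because it is a property of the
published procedure itself.

```{r}
m <- measure_object(make_object_cloud(object_spec("cuboid"),
       noise_model(jitter_sd_mm = 0, outlier_rate = 0), seed = 1))
unlist(m[1:3])
```

## Measuring plants

Plants are segmented by color, not geometry.  Per point, the triangular
greenness index

$$TGI = -0.5\,[\,0.19\,(R - G) - 0.12\,(R - B)\,]$$

is computed on raw 8-bit channels (the index is invariant to adding a
constant to all channels, and any positive rescaling leaves the
clustering unchanged, so the channel scale is immaterial).  A two-class
k-means on the TGI values separates plant from background; points that
are both in the higher-TGI cluster *and* strictly green ($TGI > 0$) are
plant — the two published criteria applied conjunctively (either alone
is available via `rule =`).  If every TGI is identical the k-means is
degenerate and the sign rule alone applies.

`kmeans_two` is deterministic and exact: Lloyd's algorithm from the
extreme initialization (min, max) followed by an exact scan of all
threshold cuts in sorted order — in one dimension the optimal 2-means
partition is a cut, so the scan guarantees the global optimum.  Lloyd
alone can stall: on $\{0, 10, 11, 21\}$ it converges to WSS 100 while
the optimum is 74.  Because the procedure has no random step, it takes
no seed.

Plant height divides the plant z values (measured from the bed plane,
estimated as the 1st percentile of background-point z, since pots sit
above the bed) into 50 equal-width bins and averages the z of the
highest-edge non-empty bin — the canopy top, insensitive to lower leaf
layers.  The 50-bin histogram is taken over plant-only z (the procedure
leaves this open; using all z would let bed points stretch the range).

```{r}
pc  <- make_plant_cloud(plant_spec(plant_height_mm = 300), seed = 1)
seg <- segment_plant(pc)
seg
plant_height(pc$xyz[seg$plant_idx, 3])
```

## Accuracy analysis

`abs_errors` computes $|measured - truth|$ per object, dimension and
POU.  `fit_power` fits $err = a\,POU^{\,b}$ by ordinary least squares on
the log–log scale (the fitting method is not specified in the original
analysis; log-OLS is the standard choice, and $R^2$ is reported on the
transformed fit with an original-scale pseudo-$R^2$ alongside).  Exact
zero errors — which do occur — are floored at 0.01 mm before the log,
and the count of floored values is reported.  `agreement_stats` reports
the OLS slope/intercept/$R^2$ of automated on manual measurements plus
the RMSE against the 1:1 line (the RMSE *between methods*, not the
regression residual).  `one_way_anova` is the textbook between/within
decomposition with unadjusted pairwise pooled-variance t tests (the
least-squares-means PDIFF analogue; adjustment available but off by
default, matching the original analysis).  The shape-by-dimension error
table is handled as one-way ANOVA within dimension; a full factorial GLM
is out of scope.

## The synthetic world

No greenhouse imagery or commercial SfM reconstructions are available,
so the package carries a generator that emulates reconstruction
*output*: surfaces sampled uniformly at a density (default
1 point·mm⁻², giving the ~50 k points per object reported for the best
acquisitions), only camera-visible surfaces (top + lateral; a nadir
system never sees undersides), optional bed annulus at $z = 0$,
isotropic Gaussian jitter (default 0.5 mm), sparse outliers displaced
along the surface normal (default rate 0.1 %, offset 20 mm — the
floating specks seen around real reconstructions), and ground-truth
labels on every point.

POU-dependent degradation (`pou_degradation`) maps a POU value to:

* a density scale $(POU/556)^{0.5}$, capped at 1 — clouds thin as POU
  falls (the reported point counts drop by ~85 % from POU 556 to 17);
* a random lateral dropout growing to 0.6 as POU $\to$ 0 — side
  surfaces lose points first;
* jitter $0.2 + 5/\sqrt{POU}$ mm;
* an *erosion depth* $\delta = a\,POU^{\,b}$ (defaults $a = 200$,
  $b = -0.6$): all points within $\delta$ of the object's $+x$ and $+y$
  extremes are removed, emulating the one-sided incomplete side surfaces
  that low-POU reconstructions show.  Erosion is the mechanism that
  makes *measured* x/y error follow a power law in POU by construction;
  the defaults put the error near 4 mm at POU 556 and near 37 mm at
  POU 17, the magnitude range observed for real reconstructions.  These
  constants are configuration, not claims about any particular system.

What a green test on this world establishes: that the estimators recover
known geometry, degrade monotonically in POU, keep height error below
planimetric error, and that the statistical machinery recovers known
power laws within stated bounds.  What it does not establish: the actual
error magnitudes of any physical gantry — the generator has no image
matching, no bundle-adjustment distortion, no illumination effects, no
leaf-level plant architecture.  Empirical constants of a real system
(the published $R^2$ of 0.78/0.88 for the x/y error fits, or the case
study's $R^2 = 92\%$, RMSE 9.4 mm against manual heights) are context,
not reproduction targets.

The synthetic plant is an ellipsoidal canopy shell over a thin stem with
green-dominant RGB ($G > R$, $B \le R$, so $TGI > 0$ before noise) on a
dark near-gray bed ($TGI \approx 0$); the canopy apex is pinned exactly
at the nominal plant height.  Colors are 8-bit, as delivered by a
camera.

All generators are deterministic given (spec, seed); the experiment
driver derives per-cloud seeds from the master seed, keeping every
derived seed below $2^{31}$.

## Known limitations

* Mushroom x/y under-reads the cap diameter (documented above).
* The 1 %-percentile floor estimate biases heights upward by about
  $1.4\sigma$ of the jitter when the bed is noisy — small relative to
  planimetric errors, and the reason the z error curve is flat but not
  zero.
* The erosion model degrades $+x/+y$ sides only; real incompleteness
  hits random sides.  Since the extractors are axis-symmetric, this
  loses no generality for error magnitudes.
* `run_full_evaluation`'s fitted exponents are shallower than the
  erosion exponent because subsampling and dropout add error components
  that are not themselves power laws; only the sign of $b$ is a stable
  qualitative claim.
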