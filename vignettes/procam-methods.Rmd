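---
title: "Methods: scan-zone calibration and closed-loop wound targeting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scan-zone calibration and closed-loop wound targeting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(procam)
```

## The problem

A projector-coupled incubator microscope steers patterned light onto living
samples while a camera watches the same field. Before any targeted
illumination is possible, the instrument must know which projector pixel
lights which camera pixel. Because the projector and camera view the sample
plane from different angles through different optics, the relationship is a
general planar affine transform — six parameters covering rotation,
anisotropic scale, shear and translation — not a simple scale-and-shift.

`procam` implements three layers:

1. **calibration** — a structured-light scan-zone procedure that estimates
   the camera-to-projector affine map, with auto-tuning of its
   hyper-parameters from simple grid observations;
2. **wound targeting** — segmentation of a scratch-assay brightfield image,
   extraction of the leading wound edge, and conversion of that edge into a
   projector pattern;
3. **closed loop** — a scheduler that re-runs targeting at fixed intervals so
   the projected pattern follows the migrating edge.

Everything runs against a **virtual optical bench** that simulates the
projector-to-sample-to-camera light path, so the full stack is testable with
no hardware attached. The same code drives real rigs through the folder-bench
backend, which exchanges pattern and capture images through the file system.

## Calibration procedure

The five steps:

1. Illuminate every projector pixel and threshold the lit-minus-dark camera
   difference image to find the **illuminable region** — the camera pixels the
   projector can reach. The largest connected component is kept, which
   discards stray-light artefacts near the border.
2. Sweep bands of `l_p` adjacent projector **columns**, recording the mean
   intensity in each scan zone per band.
3. Repeat the sweep over projector **rows**.
4. For each zone, locate the column and row band positions with the highest
   measured intensities; combined they give the zone's projector-frame
   coordinates.
5. Fit the six-parameter affine map from the camera/projector point pairs by
   least squares.

A **scan zone** is a small square of camera pixels used as a photometer.
Each zone yields one correspondence, so at least three non-collinear zones
are needed; the default is four (one per corner direction of the region's
bounding box), which adds least-squares redundancy and a meaningful residual.

### Zone placement and the border variable

Accuracy favours placing zones as far apart as possible, but zones hugging
the region border risk measuring stray light. The border variable
`b` in [0, 1] interpolates between the two regimes: per axis, the zone-centre
offset from the bounding-box centre is

    offset(b) = (1 - b) * h + b * (s_c / 2)

with `h` the bbox half-extent and `s_c` the zone breadth. At `b = 0` centres
sit exactly on the bbox border; at `b = 1` the four zones pack mutually
adjacent around the centre. `b = 1/3` is an effective default. Because a
rotated or clipped footprint need not fill its bounding box, each zone
measures over (and takes its camera-side correspondence point from) the
intersection of its square with the illuminable mask; zones whose square
misses the mask entirely are nudged inward along their corner diagonal.

### Hyper-parameter auto-tuning

For the peak search to be well-conditioned, at least two scan lines should
intersect each zone, so the zone breadth in camera pixels is twice the
camera-frame scan-line breadth:

    s_c ~ 2 l_c,   l_c = M l_p

`M` is the projector-to-camera magnification. It is estimated *before* any
map exists by projecting a grid with spacing `G_p` (projector px),
superimposing a reference grid with spacing `G_c` (camera px) on the camera
view, and comparing observed square sizes `g_p` and `g_c`:

    g_c / G_c ~ M g_p / G_p     =>     s_c ~ 2 l_p g_c G_p / (G_c g_p)

The subscript convention here follows the relation as stated; on the virtual
bench, `measure_grid_observations()` reports the projected-square size in
units of reference-grid squares as `g_c` with `g_p = 1`, which recovers the
true scale when `G_p = G_c` (the configuration the automated path uses). The
grid spacing is measured from the autocorrelation of the detrended,
footprint-cropped intensity profile, which tolerates rotation, blur and
partial coverage. `s_c` is rounded up to the next odd integer so a zone has a
well-defined centre pixel; the relations themselves only claim approximate
equality.

`l_p` trades accuracy against scan time: the profile is sampled once per
band, so fewer, wider bands are faster but coarser. As a rule of thumb the
suite keeps `l_p` near 2.5% of the projector extent (10 on a 640-px
projector, 4 on the 160-px test projector).

### Peak localisation

Within a band sweep, the zone's intensity profile is (to first order) the
overlap area between the moving band and the zone square: a plateau with two
partial edge bands. Two locators are provided:

- **Photometric centroid** (default). Because an affine map sends region
  centroids to region centroids, the intensity-weighted centroid over the
  full contiguous support of the peak is an (almost) unbiased estimate of the
  zone's projector position. Two refinements matter at this precision:
  - *pixel-centre convention*: band `k` covers projector pixels
    `k l_p ... (k+1) l_p - 1`; with pixel centres at integer coordinates its
    photometric centre is `(k + 0.5) l_p - 0.5`. Omitting the half-pixel term
    biases every estimate by +0.5 px.
  - *edge-band correction*: a partial edge band holds light only in a strip
    of width `lambda` at its inner side, so its centre is placed `lambda / 2`
    inside the inner band edge rather than at the band midpoint. With this
    correction the locator is exact on noise-free benches.
  Cutting the profile at a high fraction of the peak (e.g. half-maximum)
  discards asymmetric tails and biases the estimate by up to half a band,
  which is why the support floor is a low 5% of peak.
- **Argmax** (`use_centroid = FALSE`): the band with the highest intensity,
  ties broken toward the lower band index — the strictly literal reading of
  "highest measured intensities", retained for comparison.

Zones whose peak contrast falls below `contrast_floor_mads` times the
dark-frame MAD are dropped with a warning; calibration fails if fewer than
three usable zones remain.

## The virtual bench

`render_camera_view()` composes, in order: scene brightfield base (or a flat
background), plus the projector pattern warped through the ground-truth
projector-to-camera map and masked to the illuminable footprint; then radial
vignetting, Gaussian blur, additive Gaussian read noise, and clipping to
[0, 255]. Noise is seeded from the bench seed plus a content hash of the
pattern and scene state: identical captures are bitwise identical (renders
are reproducible), while different patterns in one calibration see
independent noise — without this, dark-frame subtraction would cancel the
noise exactly and flatter the calibration.

When no ground-truth map is given, the bench constructs a centred pure-scale
map whose warped projector rectangle occupies `illum_coverage` of the camera
frame.

### The scratch-assay scene

The simulated monolayer emulates a 10x brightfield scratch assay at
1.25 um/px: textured mid-gray cells (default 140) against a brighter open
wound (default 200), with band-limited static texture. The wound is a
vertical band bounded by two fronts stored as per-row sub-pixel positions
`x_left(y)` and `x_right(y)`. This height-function representation keeps each
front connected by construction, makes the ground-truth edge polylines exact
(the evaluation oracle costs nothing), and makes wound area strictly
decreasing while healing. Its price is that overhangs, islands and
multi-valued fronts cannot be represented; those regimes are outside what the
detector is validated on.

Front dynamics: each front row advances into the wound at `v dt` pixels
(`heal_rate_v` in um/h over the 1.25 um/px pitch); a row whose front lies
within `light_reach_px` of an illuminated camera pixel advances at
`v (1 + g) dt`. The light response is deliberately local — only illuminated
front rows accelerate — mirroring the targeted-illumination premise that
the leading edge, not the bulk monolayer, is the control surface. Defaults
`heal_rate_v = 8` um/h and `g` in [0, 1] are stated configuration, not
measured biology: epithelial scratch closure rates of a few to
~15 um/h are typical, and no migration rate is claimed for any specific cell
line. Where fronts would cross within a step they stop at the meeting point;
a closed wound is a fixed point.

## Wound targeting

`segment_monolayer()` applies a percentile contrast stretch (2–98% by
default; CLAHE optional), Otsu or fixed thresholding, morphological
closing/opening with a disc brush, and small-object removal. Polarity is
chosen automatically as the larger-area class, which in a scratch assay is
the confluent monolayer surrounding the wound band; it can be forced.

`extract_wound_edge()` traces the mask's sub-pixel iso-contours at level 0.5
(marching squares via `grDevices::contourLines`), discards vertices within
`edge_margin_px` of the image border — a frame border is never a wound
edge — splits contours at the discarded gaps, and returns the longest
remaining chain by polygonal arc length as the leading edge. The chain is
lightly smoothed (5-vertex moving average) and Douglas-Peucker simplified at
0.5 px before use, bounding the coordinate payload sent to the projector. A
`both_fronts` mode returns the two longest chains for symmetric-illumination
experiments.

`edge_to_pattern()` maps the edge through the calibration and rasterises it
with the requested stroke thickness; a pixel is on iff its centre lies within
`thickness / 2` of the polyline, and the pattern is clipped to the projector
frame (an edge mapping wholly outside warns and yields an all-off pattern).

## Closed loop

`build_schedule()` fixes the endpoint convention: both timelines include
t = 0 and every multiple of their period up to the duration, so 5-minute
imaging over 24 h gives 289 captures and 30-minute projections over 6 h give
13 projections. The projection period must be a multiple of the imaging
period so projections always have a fresh frame.

`run_loop()` decouples simulated time from the wall clock: the virtual bench
advances by schedule deltas (a hardware adapter would sleep instead — the
engine never assumes which). Between events the scene is stepped with the
illumination the sample *actually receives*: the projected pattern warped to
the camera frame through the bench's ground-truth map, not the intended
camera-frame edge. Each projected pattern stays on for `exposure_min`
(default: the full projection period); the exposure duration is a required
configuration choice with no claimed biological default. A failed edge
detection logs a warning and re-projects the previous pattern — the loop
never aborts on a bad frame. On the virtual bench every projection record
carries the tracking error (mean distance of back-mapped pattern pixels to
the ground-truth edge) plus the true front positions, for evaluation only.

`render_timelapse()` writes per-capture RGB overlays (edge in light blue,
back-mapped pattern in magenta) as a numbered PNG frame stack; no video
encoder is bundled.

## Problem sizes and what the tests show

The package defaults are full-size frames (1920 x 1088 camera, 640 x 360
projector, `l_p = 10`). The test and acceptance suites run the same
algorithms on 480 x 270 / 160 x 90 benches with `l_p = 4` — the same
fraction of the projector extent — with 150-um wounds, noise sigma up to 4
and blur up to 2 px; a 6-h loop with 30-minute projections is simulated in
full. These sizes were chosen so the whole suite runs in minutes on one core
while preserving the geometry of the full-size problem.

Passing tests demonstrate: sub-2-px median map recovery across random
benches (rotation to 10 degrees, scale 0.5–2, translation to 25% of frame);
banded-scan/brute-force agreement; sub-2-px edge detection on noisy
sinusoidal fronts; pattern-on-edge tracking through a simulated 6-h loop; and
faster closure of light-responsive wounds under closed-loop illumination.
They do *not* demonstrate performance on real micrographs: the simulator has
no uneven illumination drift, no debris or floating dead cells, no
phase-contrast halo, no focus drift, and its light response is a clean
deterministic gain rather than a dose-dependent biological effect. The
segmentation defaults will need adjustment on real data; the geometry stack
(calibration, mapping, rasterisation) transfers unchanged.

## Known limitations

- The affine model cannot absorb lens distortion or projective keystone
  beyond first order; residuals on a real rig will include that model error.
- Magnification auto-measurement assumes the projected grid is resolvable in
  the camera image; at extreme minification the grid lines blur together and
  `G_p` must be raised.
- The scene model is a band wound with single-valued fronts; island
  re-epithelialisation and multi-wound fields are out of scope.
- The folder bench trusts file naming for pattern/capture pairing; there is
  no hardware handshake.
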