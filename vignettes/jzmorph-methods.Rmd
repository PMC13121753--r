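---
title: "Methods and conventions of the jzmorph pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and conventions of the jzmorph pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jzmorph)
```

`jzmorph` quantifies junctional-zone morphogenesis from upstream tracking
and segmentation output. This vignette is the package's own account of the
measurement models, their assumptions, the tunable parameters, and the
numerical choices made where the design was genuinely open. It states no
empirical result that the test suite and `scripts/acceptance.R` do not
themselves compute.

## Coordinate conventions

All tables carry real-valued micrometres; pixel-to-micrometre conversion
happens only inside image operations through `pixel_size_um`. Rasters are
2-D, y-down, row-major, with pixel centers at integer coordinates, and
label images are 16-bit-capable non-negative integers. A `tissue_frame()`
fixes the midline position, the half-width (midline to lateral edge), which
coordinate carries each tissue axis, which dorsoventral direction is
ventral, and the region scheme. Two region schemes coexist in practice —
equal thirds of each half, and a fixed 100 µm band at the midline and at
each lateral edge — so both are implemented and every analysis records
which one it used. The half-width itself is rarely given by the upstream
export; `estimate_half_width()` defaults to the 95th percentile of starting
|ML − midline| distances, which is robust to a handful of stray lateral
tracks, and can always be overridden.

## Trajectory analytics

Registration subtracts a per-timepoint landmark position (linearly
interpolated between its support points) so embryo-scale drift is removed;
origin subtraction then makes every trajectory start at (0, 0, 0) without
touching step vectors. Convergence is defined midline-relative,
`|x_start − midline| − |x_end − midline|`, because a side-signed definition
becomes ambiguous for the minority of cells that cross the midline.
Ventral displacement is `ventral_sign · (dv_end − dv_start)`.

Polar directionality histograms project each trajectory into the in-plane
(XY) or transverse (XZ) plane. Angles are degrees in [0°, 360°), 0° along
the +ML axis, counterclockwise, with half-open bins `[lo, hi)` so boundary
angles bin deterministically; the default bin width is 20°. Each sector's
weight is count × mean displacement magnitude. The unit of contribution is
deliberately configurable: the default `"net"` mode gives each track one
vote — the angle of its net displacement vector — which matches per-track
displacement weighting; `"step"` mode lets every inter-frame step
contribute instead. Which unit the original analyses used is not
derivable from their description, so neither is asserted; the default is
the one with a per-cell interpretation. Zero-magnitude vectors carry no
direction and are excluded with a reported count; an input with no
non-degenerate vector is an error rather than an empty histogram.

Displacement profiles bin tracks by normalized starting distance into ten
intervals `(0, 10%], …, (90%, 100%]` and report mean ± sem per bin (sem
uses the n − 1 sample SD throughout the package). Empty bins are reported
with n = 0 rather than dropped, so bin counts always sum to the number of
records.

## Cell geometry and intensity

`extract_cells()` takes area as pixel count × pixel size² and the boundary
as the traced outer contour. One numerical subtlety matters: contour
vertices are pixel *centers*, which sit about half a pixel inside the true
object boundary. The boundary polygon is therefore pushed 0.5 px radially
outward; without this, the cortex/cell area ratio on a rasterized disk
converges to 0.64·(1 − 1/r) instead of 0.64, a visible bias at r = 100 px.

The apical cortex is defined in polar coordinates about the centroid: a
pixel at angle θ and distance r is cortical iff r ≤ f · R(θ) with f = 0.8
by default, where R(θ) is the distance to the *first* boundary crossing
along the ray at θ — computed as the exact ray–polyline intersection, i.e.
linear interpolation between boundary samples. The first-crossing rule
presumes star-shaped cells: for a cell with distal lobes the mask
under-covers the lobes, which is accepted and documented, since epithelial
apical outlines (and the tessellations the generator produces) are
convex-ish. If a pathological concavity puts the centroid outside the
polygon, the most boundary-distant interior pixel serves as the pole and
the fallback is logged. For convex cells the mask is provably the polygon
scaled by f about the centroid, which is what the oracle tests exploit,
and the area ratio converges to f² = 0.64 as pixel size shrinks.

Junction polarity uses the chord between the junction's endpoints even for
curved junctions (matching how segmented-line overdrawing is used in
practice: endpoints set the angle, the full polyline collects intensity).
The acute chord angle to the ML axis classifies the junction: ML below
45°, AP above; *exactly* 45° classes AP, the strict reading of "less
than", and the tie rule is recorded on the output. The per-ROI polarity
ratio is the ratio of class mean intensities — not the mean of per-vertex
junction-pair ratios — because the class-means form is well defined for
any junction sample and invariant under relabeling; the vertex-paired
alternative requires a pairing that overdrawn junction tables do not
reliably carry.

Nuclear positivity is background-referenced: the background is every pixel
outside every nucleus (no dilation margin by default; one is available),
summarized by its mean and *population* SD — the population form is chosen
for determinism of the definition, and at typical background pixel counts
the sample/population distinction is far below measurement noise. A
nucleus is positive iff its mean exceeds mean + k·SD strictly, k = 2 by
default, making the classifier monotone in intensity and anti-monotone in
k.

Relative depth is D/(D+V) × 100 %, 0 % at the dorsal surface; histograms
use half-open 10 % bins with the last bin closed at 100 so totals are
conserved, and the dorsal/middle/ventral thirds cut at exactly 100/3 and
200/3 — one consistent definition reused everywhere a "third" is reported.

## Constriction kinetics

Each apical-area series is normalized by its largest area and aligned so
time 0 is the maximum, ties broken to the earliest occurrence (a constant
series aligns at its first timepoint). Aggregation averages over the cells
present at each aligned timepoint and suppresses timepoints supported by
fewer than `min_n = 3` cells. Ingression is the first timepoint where the
normalized area is strictly below the threshold (0.1 by default) *and
never recovers* — the persistence rule exists because segmentation flicker
produces transient sub-threshold dips that are not ingressions — or, for a
label that disappears before the end of the observation span without
sampling a sub-threshold area, one frame interval after its last sample.
The strict-inequality sampling convention means a sample lying exactly on
the threshold does not trigger the call; with discrete sampling the
recorded time is the first frame strictly past the continuous crossing.

## Statistical wrappers

`compare_means()` defaults to Welch's unequal-variance t-test for unpaired
comparisons — the safer default when nothing is known about the variances
— with the pooled-variance form one flag away; paired comparisons pair by
position. Degenerate inputs are reported rather than thrown: identical
groups give statistic 0 and p = 1, a constant non-zero paired difference
gives p = 0, both flagged. `compare_distributions()` wraps the two-sided
two-sample Kolmogorov–Smirnov test. No multiple-testing correction is
applied anywhere, by design. Significance stars follow the conventional
bands (ns > 0.05, then \*, \*\*, \*\*\*, \*\*\*\* at 0.05, 0.01, 0.001,
0.0001).

The calibration check in the acceptance suite runs both wrappers under the
null 2000 times at n = 100 per group. The group size is a deliberate
choice: the two-sample KS statistic is discrete, and at small n the
achievable test size near α = 0.05 drops below the nominal level by
discreteness alone, which would measure the KS null distribution rather
than the wrapper; at n = 100 the asymptotic p-value is accurate and both
empirical sizes are expected inside [0.035, 0.065].

## The synthetic generators

The generators exist so every estimator can be checked against known
truth; their defaults are the study conditions the analyses target.

`gen_tracks()`: starts uniform over [−150, 150] µm (half-width 150 µm),
180 min of imaging at 10 min intervals. Convergence follows a linear
gradient — a cell starting at normalized distance d drifts toward the
midline at `v_conv · d` with v_conv = 0.18 µm/min, so the cohort mean
convergent displacement is v_conv·T/2 ≈ 16.2 µm over 3 h. Ventral drift
(0.035 µm/min, i.e. 6.3 µm over the session) applies only at steps where
the cell currently sits within the 50 µm medial band; because that gate
depends on the realized path, the ground truth records the
exactly-integrated ventral drift per track, so downstream expectations
need no re-simulation. Per-step isotropic Gaussian noise (1 µm SD) is the
diffusion model. One caveat is inherent to the convergence definition:
near the midline, noise makes `|x_end|` a folded-normal variable, so the
observed convergence of the innermost cells sits slightly below the drift
integral; at the default noise scale this bias is a fraction of the
3-SEM recovery band the tests use.

`gen_epithelium()`: a Voronoi-like tessellation grown from jittered grid
points — convex-ish cells, so the polar cortex transform is well posed.
Jitter is capped at 0.45 of the spacing, which makes the 3 × 3
grid-neighbourhood nearest-seed search exact. Junction pixels are the
shared 4-neighbour boundaries; each junction's recorded angle is its
endpoint-chord angle — the same quantity `junction_orientation()` computes
— so the generation-time class and the analysis-time class agree by
construction, and a painted ML/AP factor f is recovered exactly at zero
noise. Vertex pixels claimed by several junctions are painted with the
maximum class value and excluded from per-junction means. Cortical patches
(disks at 0.4 of the cell radius, inside the 80 % cortex) mark a chosen
subset; the nuclear channel is Gaussian background plus a positive offset
in background-SD units on a known subset of nucleus disks. All intensities
are additive-Gaussian noised, clipped at zero, and quantized to integer
grey levels as a camera would — which also makes raster round trips
bit-exact. What the generator does *not* emulate: point-spread blur,
shading/vignetting, shot-noise statistics, segmentation errors, curved
tissue topology, or non-convex cell shapes. Passing tests therefore show
the measurement chain is correct on clean segmented input, not that
upstream segmentation is reliable.

`gen_constriction_set()`: a plateau at the per-cell maximal area
(uniform 80–120 µm²), then for ingressing cells a linear decay at a set
fraction per minute; rows stop when the true area reaches zero, mirroring
disappearance from the dorsal surface. `gen_depth_sections()` draws
relative depths from a requested mixture over thirds (uniform within the
chosen third) and converts them to D/V pairs under a 40–60 µm thickness.

## Problem sizes and reproducibility

The test and acceptance workloads use 500-track cohorts over 5 seeds for
drift recovery, 144-cell epithelia for polarity, ten 1024-cell nuclear
fields for classifier operating characteristics, 2000 cells for depth
mixtures, 2000 replicates for test calibration, and rasterized disks at
radii 25/50/100 px for the cortex limit (tolerances ±0.02, ±0.01,
±0.005) — sizes at which every binomial or SEM-based recovery band is
meaningfully narrow while the whole suite stays fast. All randomness is
seeded; `simulate`/`analyze`/`report` runs with the same seed write
byte-identical tables, which the acceptance suite asserts.

## Known limitations

* The cortex transform under-covers non-star-shaped cells (first-crossing
  rule) and relies on a centroid-interior assumption with a logged
  fallback.
* Convergence near the midline carries the folded-normal bias described
  above; it is a property of the |x|-based definition, not of the
  implementation.
* The polarity ratio is an ROI-level class-mean ratio; it does not model
  per-vertex pairing and is undefined for ROIs missing a class (flagged,
  never imputed).
* Track tables assume the minimal CSV schema documented in
  `read_tracks()`; mapping a particular vendor export onto it is the
  caller's responsibility.
* 3-D/4-D rasters, proprietary microscope formats, segmentation itself and
  curved-surface projection are out of scope; the package consumes their
  products.
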