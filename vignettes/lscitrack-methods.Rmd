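---
title: "Tracking ROIs and quantifying perfusion in laser speckle contrast imaging"
author: "lscitrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking ROIs and quantifying perfusion in laser speckle contrast imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lscitrack)
```

# The problem

Laser speckle contrast imaging (LSCI) measures superficial microvascular
perfusion over a whole field of view. A clinical foot recording runs for
minutes through three timespans of interest (TOIs): a baseline, the
post-occlusive reactive hyperemia (PORH) test — perfusion overshoots
after an occlusion cuff is released — and the Buerger's leg-elevation
test. Four elliptical regions of interest (ulcer, ulcer edge, toe, whole
foot) are drawn on the first frame, but the foot moves, so the ROIs must
be repositioned on every frame. This package automates the
repositioning and the downstream quantification; the only manual inputs
per recording are two ROI-set drawings (frame 1, and the first Buerger
frame, where the foot is deliberately repositioned) and one
artifact-exclusion box.

# Perfusion model

Over the valid pixels of an ROI in one frame, the speckle contrast is
$K = \beta\,\sigma/\langle I\rangle$, where $\langle I\rangle$ and
$\sigma$ are the mean and standard deviation of the pixel intensities
and $\beta$ is the instrument's coherence factor. Perfusion in perfusion
units (PU) is $P = k\,(1/K - 1)$ with signal gain $k$. The two-point
calibration fixes both constants: $\beta = \langle I\rangle/\sigma$ of a
zero-perfusion target forces its contrast to exactly 1 (hence 0 PU), and
$k$ is solved so a motility standard (colloidal polystyrene suspension)
measures exactly its reference value, 250 PU by convention.

Choices worth making explicit:

* **Population standard deviation** (divide by $N$). The manufacturer's
  convention is unpublished; for ROIs of hundreds of pixels the two
  conventions differ negligibly, and the population form makes small
  worked examples deterministic. The convention is recorded in the
  calibration JSON and in `metadata()` of every trace.
* **Spatial per-frame statistics.** Contrast is computed from the ROI's
  own pixel statistics per frame, not from a sliding-window contrast
  map and not across frames (temporal contrast is out of scope).
* **No clipping of $K > 1$.** Sampling noise can push a measured
  contrast above 1, giving a slightly negative perfusion. Clipping
  would bias TOI means upward, so negative values are kept and counted
  in `metadata()$n_contrast_above_one`.
* **Minimum 25 valid pixels** per ROI per frame; below that the
  $\sigma$ estimate is too unstable and the frame's value is reported
  missing (with a warning), never fabricated.
* Intensities are linear arbitrary units; the only transformation
  applied is the cast to double.

# Coordinates and rigid motion

One convention everywhere: 1-based pixel-center coordinates with
$x$ = column (rightward) and $y$ = row (downward), the natural indexing
of R matrices. Rotations are counter-clockwise in that $(x, y)$ frame
and act about the coordinate origin; the translation absorbs any pivot.
This is exactly the form the registration returns, and
`transformEllipse()`, the tracker and the simulator all share it (the
test suite checks them against each other on common fixtures).

# Tracking

For every frame the *reference* frame's foot silhouette is registered
directly onto that frame's silhouette (reference-to-frame-$n$, never
chained frame-to-frame, which accumulates drift), and the fitted rigid
transform — rotation + translation only, no scaling or reflection — is
applied to the reference ROI set.

**Silhouette extraction.** Canny edge detection: Gaussian smoothing
($\sigma = 2$ px by default; scale it with image resolution, e.g.
$\sigma = 5$ for images ~2.5x the default 200 px foot length — the
speckle-noise gradient falls faster with smoothing than the silhouette
step gradient), Sobel gradients, non-maximum suppression, and hysteresis
with auto-set thresholds (high = 90th percentile of non-zero gradient
magnitudes, low = 0.4 x high; percentile thresholds adapt to the
contrast regime, which changes during occlusion). Only the largest
8-connected edge component is kept: the silhouette dominates, interior
speckle-noise chains would corrupt the point set, and keeping secondary
chains proved worse than a partial silhouette because a borderline chain
can pass the size cut in one frame and fail it in the next, making the
frames' point sets inconsistent. Detection is restricted to the
artifact-free box drawn once on frame 1, which excludes static bright
structures (examination bench, pressure cuff) from the point sets.

**ICP.** Point-to-point iterative closest point: nearest-neighbor
correspondence followed by the closed-form 2D Kabsch fit (rotation from
the SVD of the cross-covariance, determinant constrained to $+1$),
iterated until the trimmed RMS residual changes by less than
`convergenceTol`. Numerical choices that mattered:

* **Tight tolerance (1e-5 px) and a 200-iteration cap.** On dense
  closed contours the nearest-neighbor metric barely penalizes sliding
  tangentially along the curve, so ICP creeps slowly; a loose tolerance
  freezes it mid-creep.
* **Trimming with a residual floor.** A fraction (`trimFraction`, 0.1)
  of the worst correspondences may be discarded per iteration for
  robustness, but only if their residual also exceeds `trimFloor`
  (3 px). A pure worst-fraction trim discards exactly the
  high-curvature toe points that pin down the rotation and settles in
  an under-rotated fixed point.
* **Cold-start initialization.** The sliding local minima have a
  convergence basin of only a degree or two, so cold starts initialize
  by centroid + principal-axis alignment (exact for same-shape point
  sets), run one ICP per rotational offset in $\pm 14^\circ$ steps of
  $2^\circ$, keep the lowest-RMS fit, and retry the $180^\circ$ axis
  flip if the best RMS is still above 1 px (partial silhouettes can
  fool the axis-direction choice). Within `trackRois()` each frame is
  instead warm-started from the previous frame's accepted transform —
  inter-frame motion is small — and only falls back to a cold start if
  the warm fit fails the acceptance gate.
* **Acceptance gate and carry-forward.** A fit that does not converge
  or whose RMS exceeds `maxRms` (5 px) is rejected; the previous
  frame's ROIs are carried forward with a diagnostic flag. A hard
  failure would make whole recordings unanalyzable; the flag keeps the
  event visible. Detection failure on a *reference* frame is fatal —
  nothing downstream is meaningful without it.

**Buerger reset.** The repositioned foot changes its imaged shape
non-rigidly, so the first Buerger frame gets its own manually drawn ROI
set and becomes the reference for the rest of the segment; its transform
restarts at the identity. A protocol with a Buerger segment but no
second ROI set is an error by design.

# Timeline

The occlusion release is an operator annotation (the cuff event is
invisible in the image). The PORH peak is searched after the release:
the trace is smoothed with a centered moving average
(`smoothingWindow` = 5 frames) and the global maximum is returned when a
strict local maximum exists; otherwise — perfusion rising onto a plateau
— the fallback returns the first frame at which the smoothed forward
difference stays below `plateauEpsilon` (1 PU/frame) for `plateauRun`
(5) consecutive frames, i.e. the maximum measured value once the
perfusion stops increasing. The peak TOI is a symmetric window of
`peakHalfwidth` (2) frames around the peak, clipped to the post-release
region. Those four constants are conservative for ~10 fps clinical
recordings and all configurable; smoothing can shift a detected peak by
about a frame on asymmetric transients, which the peak *window* absorbs.
Recording breaks (the pause while the foot is repositioned) are explicit
frame annotations; no TOI may span one, and nothing is interpolated
across them. TOI means are arithmetic means over non-missing frames,
with valid-frame counts reported.

# Agreement statistics

`iccAbsoluteAgreement()` implements the single-measures two-way
random-effects absolute-agreement ICC — ICC(2,1) — from the explicit
ANOVA decomposition, with the $MS_R/MS_E$ F test and the standard
F-based confidence interval (Satterthwaite degrees of freedom).
Single measures rather than average measures: individual assessments
are compared, and single measures is the conservative choice; the model
descriptor is carried in the result object. Reliability bands are
half-open upward (0.75 is "good", 0.90 is "excellent"), so each
boundary belongs to the stronger band; the boundary behavior is pinned
by tests. A placement is *suboptimal* when its perfusion deviates
strictly more than 10 % from the manual reference; pairs with a
non-positive reference are excluded (relative deviation undefined).
Ratings matrices must be complete; `validateAgainstManual()` applies
complete-case filtering per (ROI, TOI) cell and skips cells with fewer
than two subjects, logging both.

# The synthetic generator

`makeFootPhantom()` builds a parametric silhouette (superellipse sole +
five toe discs) with an ulcer disc, a hyperemic edge ring, and four
ground-truth ROIs placed on homogeneous patches of their regions, so
each ROI's true mean perfusion equals its configured level exactly
(defaults: foot 80, toe 100, ulcer 40, ulcer edge 120 PU). Static bright
boxes outside the silhouette emulate the examination bench.

`sampleSpeckle()` draws pixel intensities from a gamma distribution
with shape $1/K_{raw}^2$ and unit mean, where
$K_{raw} = K_{cal}/\beta$ comes from inverting the perfusion equation
at each pixel. This reproduces any target contrast in $(0, 1]$ — the
empirical $\sigma/\langle I\rangle$ of a uniform patch converges to the
target at the usual $1/\sqrt{N}$ rate — and is physically motivated by
speckle averaging (shape 1 is fully developed speckle, the exponential
intensity limit) without simulating coherent optics. Motion uses
nearest-neighbor resampling: interpolation would smooth the speckle and
artificially lower the contrast. Background is marked invalid in the
validity mask, mirroring the background exclusion of real scans.
`simulateScenario()` assembles the full clinical protocol — baseline,
occlusion at 0.2x, hyperemia overshoot to 2.5x, a break, and a
repositioned Buerger segment at 0.4x — with every per-frame pose and
per-region perfusion recorded as ground truth.

What the generator does *not* emulate: spatial speckle correlation
(pixels are independent draws), exposure-time physics, tissue optics,
non-rigid foot deformation, and illumination drift. Passing tests
therefore demonstrate the pipeline's correctness against its own model
of the data, not robustness to every property of clinical recordings —
most importantly, real Buerger repositioning is non-rigid, which is
exactly why the second manual ROI set exists.

# Problem sizes in the test suite

Chosen once from a sampling-error budget, stated here as the package's
own conditions:

* Calibration targets: 64 x 64-pixel patches, 10-20 frames. At
  $N = 4096$ the per-frame contrast SE leaves the held-out target means
  comfortably inside the 0 ± 5 / 250 ± 5 PU bands.
* Cohort bookkeeping: 66 recordings at 0.7 phantom scale, 18 frames
  each — 66 x 4 ROIs x 3 TOIs = 792 placements.
* Single-frame registration suite: 50 seeds, rotations to ±15°,
  translations to ±20 px, speckle noise on, 0.75-scale phantom.
* End-to-end region recovery: 2.5-scale phantom (ulcer ROI ~1200 px),
  45 frames, Canny $\sigma$ = 5. The speckle sampling SE of each
  region's trace mean is then a small fraction of the 5 % band; the
  binding term is the low-perfusion ulcer region, where
  $\mathrm{d}P/P = (\mathrm{d}K/K)/(1-K)$ amplifies contrast noise.

# Known limitations

* Rigid registration only; non-rigid deformation within a segment is
  not modeled (that is the motivation for the Buerger reset, and
  B-spline registration would be the natural extension).
* Point-to-point ICP on smooth contours depends on initialization;
  the multi-start machinery makes cold starts robust but costs a few
  extra ICP runs.
* The ICC confidence interval is the standard F-based approximation;
  exact small-sample coverage is not claimed.
* Perfusion estimates at low perfusion (contrast near 1) have large
  relative sampling error per frame; averaging across a TOI is
  essential, and a small positive Jensen-type bias of order
  $\mathrm{Var}(\hat K)$ remains.
* TIFF output stores float32 pages normalized by a sidecar-recorded
  scale; round-trips are exact only to single precision.
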