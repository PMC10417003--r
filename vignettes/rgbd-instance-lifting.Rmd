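---
title: "Lifting 2D instance masks to per-animal 3D point clouds: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lifting 2D instance masks to per-animal 3D point clouds: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cloudlift)
```

## The problem and the model

Overhead RGB-D monitoring of group-housed animals produces registered
colour and depth frames from a fixed camera (typically ~3 m above the pen
floor, 848x480 at millimetre depth resolution). Downstream tasks — body
measurement, condition scoring, weight estimation — need per-animal 3D
point clouds, but direct 3D annotation and 3D network training are costly.
`cloudlift` implements the alternative route: segment animals in 2D, then
lift each instance mask through the depth channel into a metric cloud.

The geometric core is the pinhole back-projection. With 0-based pixel
coordinates under the pixel-centre convention, a pixel $(u, v)$ holding raw
depth count $d > 0$ maps to the camera-frame point

$$z = d \cdot s, \qquad x = (u - c_x)\,z / f_x, \qquad y = (v - c_y)\,z / f_y,$$

where $(f_x, f_y, c_x, c_y)$ are the intrinsics in pixels and $s$ the depth
scale in metres per count ($s = 0.001$ for millimetre 16-bit PNGs). The
camera frame is right-handed with $+z$ along the optical axis away from the
camera. A count of $d = 0$ encodes "no sensor return" and is always
skipped; no point is ever emitted at the origin, and point counts are by
construction independent of the RGB content.

Instance identity is carried by a flat-colour mask image plus an ordered
colour list. Colour matching is exact — masks travel as lossless PNG, so a
tolerance would only mask pipeline bugs. The per-frame procedure is: build
the full-frame cloud from RGB + depth, build mask clouds from mask + depth,
and split them by the colour list into one cloud per instance, coloured
from the RGB frame (never from the mask). When only detection boxes and a
binary semantic-foreground mask are available, instance masks are formed by
intersection: a foreground pixel belongs to the box that contains it; a
pixel inside several boxes goes to the highest-scoring box, with score ties
broken toward the lower instance index. The tie-break mirrors
non-maximum-suppression preference and makes the construction fully
deterministic; contested pixels are never silently dropped.

## Registration and the similarity score

Lifted clouds are compared against reference clouds (e.g. manually
annotated ones) with point-to-point iterative closest point:

1. correspondences: each source point takes its nearest target neighbour
   within `max_corr_dist` (default 0.05 m — animal-scale geometry at 3 m
   range);
2. update: the closed-form least-squares rigid fit (Kabsch, via SVD of the
   cross-covariance, with the determinant correction that excludes
   reflections);
3. stop when the correspondence RMSD improves by less than `tol` (default
   1e-6 m) or after `max_iterations` (default 50).

The RMSD sequence is non-increasing while the correspondence set is stable
(each point's new nearest neighbour is at most as far as its previous
correspondent, and the Kabsch step cannot worsen the fit on fixed pairs);
the per-iteration history is returned so this can be inspected. Degenerate
correspondence sets (< 3 pairs, collinear points) are rejected as rank
deficient rather than producing an arbitrary rotation.

Two initialisations are offered. The default (`init = "none"`) starts at
the identity: clouds lifted from the same frame already share the camera
frame, and genuinely unrelated clouds should *fail* to match (no
correspondences within radius, `similarity = 0`) rather than be dragged
together. `init = "centroid"` first matches centroids — the standard choice
when an unknown rigid offset is expected, as in the recovery experiments
below; an identity start with a 5 cm correspondence radius cannot reliably
see past a 10-degree-plus-5 cm offset.

The reference literature reports cloud "similarity scores" without defining
them, so the score here is a declared stand-in, fixed and documented:
after alignment, the fraction of source points whose nearest reference
neighbour lies within `tau` (default 0.01 m), reported both directed and
symmetric (mean of the two directions). It lives in $[0, 1]$, equals 1 for
identical clouds, and is invariant under simultaneous rigid motion of both
clouds. It is *not* claimed to reproduce any externally published
similarity number: those depend on unreleased frames and manual
annotations.

## Evaluation metrics

Precision is $TP/(TP+FP)$ and is undefined (an error, not 0) when no
positive predictions exist. AP follows the standard greedy rule: sort
detections by descending score (ties keep input order), match each to the
best-IoU still-unmatched ground truth of the same image with IoU at or
above the threshold (ties to the lower index), then integrate the
precision-recall curve. Two integrations are provided: all-point
(continuous) interpolation — the default, integrating the precision
envelope exactly — and COCO-style 101-point sampling; on the test suites
they differ by well under the reporting precision. mAP@0.5:0.95 is the
unweighted mean over the ten thresholds 0.50, 0.55, ..., 0.95. The printed
formula in the source material indexes classes from 0 to $n$ over divisor
$n$; it is implemented as the mean over the $n$ classes (a single animal
class here), the only reading consistent with its verbal description.

A deployment-style confidence cut (only detections scoring above 0.9 count
as accepted) is exposed as a separate `filter_detections()` step applied
before confusion counting — never inside the AP sweep, which by definition
sweeps all scores. Box AP (rectangle IoU) and mask AP (pixel-set IoU) are
computed separately. Global pixel accuracy is the trace of the pixel
confusion matrix over its total.

## Preprocessing

Frame deduplication instantiates the "double hash" idea as aHash plus dHash
on 8x8 grayscale thumbnails (Rec. 601 luma, exact area-average resize). A
frame is dropped only when **both** Hamming distances to some already-kept
frame are within their thresholds (default 5 bits of 64 each) — requiring
agreement of two hashes reduces false drops. The first frame is always
kept; output order is preserved. Comparisons use strict `>` with a 1e-9
guard so a constant image hashes to all-zero bits regardless of resize
round-off. dHash compares horizontal neighbours, making it invariant to any
global order-preserving brightness change — a deliberate property (day and
night frames of the same scene should collapse), with the flip side noted
under limitations.

Mosaic augmentation draws a stitch centre uniformly from the central 50% of
the canvas (seeded), fills each quadrant with the corresponding input's
top-left crop of quadrant size, translates each input's boxes by exactly
its quadrant origin, clips to the quadrant, and drops boxes whose surviving
area falls below 1% of the original. Crop origins are fixed at the top-left
so the annotation transform is a pure translation; the randomness lives in
the centre jitter, which already randomises all four crop sizes. Kept plus
dropped annotations always equal the input count, per quadrant.

## The Res2Net bottleneck

The block models the hierarchical multiscale structure only: a 1x1 input
projection, a split of $C$ channels into four equal groups, the cascade
$Y_1 = X_1$, $Y_2 = K_2(X_2)$, $Y_i = K_i(X_i + Y_{i-1})$ for $i = 3, 4$
(3x3 kernels, stride 1, padding 1), concatenation, a 1x1 output projection,
and the residual sum with the block input. Activation and normalisation
layers are training-time details of the surrounding network and are omitted
by default, which makes the block linear — a property the tests exploit
(`forward(ax) = a forward(x)`). An elementwise activation hook can be
supplied. Whether the first group is convolved is genuinely open in the
source diagrams; following the original design, $X_1$ passes through
unconvolved by default, with an optional `k1` kernel. "All weights zero"
is read as including the 1x1 projections (which are convolutions), making
the zero-weight block exactly the identity map through the residual path;
with identity projections and delta kernels the internal hierarchy
$Y_3 = X_3 + X_2$, $Y_4 = X_4 + X_3 + X_2$ is exposed via
`return_hierarchy = TRUE` and checked channelwise.

## The synthetic scene generator

The generator emulates the acquisition geometry, not the photometry, of the
target setting: a fixed overhead camera (default intrinsics 848x480,
$f = 425$ px, principal point at the frame centre, millimetre depth) over a
flat floor at 3.0 m, with `n_animals` convex half-ellipsoid blobs lying on
it. Defaults encode what a scientist would call a realistic pen seen from
3 m: apex heights 0.25-0.45 m (a lying adult pig), ellipse semi-axes 55-95
by 28-50 px (bodies roughly 0.6-1.3 m long on the floor plane). Blobs are
placed fully inside the frame and non-overlapping (bounding-circle test)
unless `overlap_mode` deliberately creates the adhesion failure regime;
placement failure after bounded retries is an error, never a silent
truncation. The ellipsoid is cut at 99% of its footprint so every mask
pixel is elevated at least 10% of the apex height — mask pixels are
strictly above the floor even after millimetre rounding.

Depth noise is Gaussian in millimetres, added to the counts and clipped at
0, so heavy noise genuinely invalidates pixels and exercises the zero-depth
path. Illumination is a gamma-style (nonlinear) brightness factor applied
to the RGB path only — depth is never touched — so varying it must leave
every lifted coordinate and point count bit-identical, which is asserted as
the literal form of day/night robustness. Ground-truth clouds are the
back-projection of each instance's valid-depth mask pixels, i.e. exactly
what a correct lifting pipeline must reproduce; the end-to-end equality
test is the package's master regression.

What the generator does *not* model — photorealistic texture, animal pose
and posture, sensor-specific depth artefacts (edge bleeding, multipath),
imperfect RGB-depth registration — bounds what passing tests show: they
validate the geometry, bookkeeping and metrics of the pipeline exactly, not
detector performance on real farm imagery.

`perturb_detections()` turns a scene's ground truth into a detection set of
known composition (drop rate, per-edge jitter, and false positives injected
so the FP fraction equals `fp_rate`, placed to overlap no ground truth), so
expected precision and AP are computable analytically.

## Numerical choices and degenerate inputs

* Boxes are 0-based half-open `(x_min, y_min, x_max, y_max)`; polygon
  rasterisation uses pixel-centre even-odd fill (the 10x10 square covers
  exactly 100 pixels) — annotation pixel counts depend on the rule, so it
  is fixed and tested.
* Depth PNGs are 16-bit single-channel; reading an 8-bit file is a format
  error with a remediation hint, not a silent rescale. No installed R
  writer emits 16-bit PNG samples, so the package writes the three PNG
  chunks itself (zlib via `memCompress`, CRC32 in C); `png::readPNG`
  verifies every file bit-exactly on the way back.
* PLY is ASCII (diff-able fixtures) with six decimal places — micron-level
  at metre scale; non-finite coordinates are refused with a count. Unknown
  vertex properties in foreign files are ignored.
* ICP convergence is declared when RMSD improvement drops below `tol` or
  RMSD itself is at most `tol` (identical clouds converge in one
  iteration). Empty clouds, zero thresholds and rank-deficient
  correspondence sets raise errors.
* All stochastic components (scene generation, detection perturbation,
  mosaic jitter) run under an explicit seed through an RNG-state-preserving
  wrapper, so library calls never disturb the caller's random stream and
  identical seeds give bit-identical outputs.

## Problem sizes used by the test suite

The suite validates lifting on 25 full-size (848x480) scenes with 2-8
instances each, clean and with 25 mm depth noise; ICP recovery on 100
seeded perturbations (up to 10 degrees and 5 cm, centroid-initialised) of a
2,000-point instance cloud, at 0.1 degree / 1 mm tolerances; AP against an
exhaustive prefix-rematching oracle on 200 random toy detection sets at all
ten IoU thresholds to 1e-9; and the Res2Net forward against a nested-loop
convolution oracle to 1e-9. These sizes were chosen so the whole suite
completes in about a minute while still exercising every code path at the
default study geometry.

## Known limitations

* The similarity score is a documented stand-in; published similarity
  figures for real herds cannot be checked without their frames and manual
  annotations.
* Perceptual hashes are intentionally robust to global tone changes, so a
  pure illumination change does not alter them; deduplication across a
  day/night boundary therefore relies on content differences, not
  brightness.
* Nearest-neighbour search is brute force (C++); it is sized for
  per-instance clouds (thousands of points), not for dense full-room scans.
* Rigid registration only — no scale estimation, no non-rigid deformation,
  no global pose search; clouds are assumed metric and roughly pre-aligned
  (same sensor, same frame).
* Box-based instance construction inherits 2D failure modes: heavily
  adherent animals whose boxes overlap strongly cannot be separated by a
  box-and-semantic-mask intersection, which `overlap_mode` reproduces for
  stress testing.
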