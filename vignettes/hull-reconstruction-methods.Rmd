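---
title: "Hull reconstruction-reprojection pose estimation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hull reconstruction-reprojection pose estimation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(flyhull)
```

# The problem

Free-flying fruit flies beat their wings at roughly 200-270 Hz. Multi-camera
high-speed videography captures their flight as synchronized binary
silhouette sequences, and the analysis task is to recover, per frame, the
standard 12 degree-of-freedom pose: body position, body orientation (yaw,
pitch, roll), and three Euler angles per wing (stroke `phi`, elevation
`theta`, pitch `psi`), plus the spanwise wing deformation profile. The hard
part is occlusion: wings cross the body outline and each other in individual
views, so no single camera sees a full wing at all times.

`flyhull` implements a model-free hull reconstruction-reprojection approach.
Silhouettes from all cameras are carved into voxel hulls; part-specific
*expanded hulls* resolve which voxels belong to each wing even when a wing is
partially or completely hidden in some views; the wing hulls are then
reprojected back to the image planes, which reveals the occluded wing pixels
and lets the leading and trailing edges be reconstructed in 3D. All angles are
read off these hulls; no articulated model is fitted to the images.

# Geometry and conventions

Stated once and used everywhere:

* **Lab frame**: right-handed, z up, meters. **Image frame**: x (column)
  right, y (row) down, pixel centers at integer coordinates, 1-based.
* **Camera model**: one 3x4 DLT-style projection matrix per camera; no lens
  distortion (synthetic data need none; real footage can be pre-undistorted).
  Continuous pixel coordinates are snapped to integers by
  round-half-away-from-zero; carving results depend on the rounding rule,
  which is why it is a named primitive (`round_half_away`).
* **Body frame**: `x_b` forward (tail to head), `y_b` left, `z_b` up;
  orientation matrices map body to lab coordinates, columns are the body
  axes. Yaw-pitch-roll is the Z-Y-X sequence of `body_rotation()`.
* **Stroke plane**: normal `n_sp` obtained by rotating `x_b` by -45 degrees
  about `y_b`; equivalently `n_sp = (x_b + z_b)/sqrt(2)`.
* **Wing angles**: `phi` is the azimuth of the span's in-stroke-plane
  projection measured from the body-backward direction, increasing frontward
  (so the front stroke is the per-beat maximum of `phi` and pure lateral is
  90 degrees); `theta` is the elevation of the span above the stroke plane;
  `psi` rotates the chord about the span, with `psi = 0` for a wing lying in
  the stroke plane and `psi = 90` for a wing plane perpendicular to it. The
  chord points from the trailing toward the leading side. Left and right
  conventions are mirror images, so mirrored poses give equal triplets.

Absolute zero references for `phi` and `psi` are a convention choice; other
self-consistent choices differ from ours by constant offsets. Validation is
therefore performed on error series after removing the per-angle median
error, and the forward-inverse consistency of the conventions themselves is
tested exactly (`wing_vectors_from_angles()` /
`wing_angles_from_vectors()` round-trip to 1e-6 degrees).

# Pipeline stages

## Motion-based segmentation

A wing sweeps past any given pixel only briefly during a wingbeat while the
body occupies its pixels continuously. `segment_body()` exploits this in two
passes: (1) sliding-window occupancy over one wingbeat window (default 73
frames, matching ~250 Hz wingbeats filmed at ~18 kHz; `window = "auto"`
estimates the period from the autocorrelation of the total fly-pixel count);
pixels occupied at least `occupancy_fraction` of the window (default 0.85)
form a provisional body mask and 2D body center of mass (CM); (2) each frame
is shifted by its integer-pixel CM displacement, the occupancy is recomputed
on the aligned stack, and the final mask is shifted back. Integer shifts are
used because sub-pixel shifts would break binary masks. Stack ends use
truncated, re-normalized windows.

## Hulls

A voxel grid (cube of side 2.6 wing lengths, pitch defaulting to one
image-pixel footprint at the chamber center — finer adds no information)
is centered on the body CM triangulated from the per-camera 2D CMs by linear
least squares, and rebuilt only when the CM drifts by more than 5 voxels.
`carve()` keeps a voxel iff its rounded projection is foreground in every
camera; voxels projecting outside an image count as *not seen* and are
rejected, which keeps hulls inside the covisible volume. Per frame the
pipeline builds:

* the body hull (body masks in all views);
* four expanded body hulls (body mask in one view, full-fly masks
  elsewhere) and their majority hull (voxels in at least two);
* up to eight expanded wing hulls (one wing connected component in one
  view, full-fly masks elsewhere; a merged two-wing component is used once
  for both wings);
* the combined wing hull: union of the expanded wing hulls minus the
  majority body hull — this removes body voxels and most wing-body
  occlusion artifacts;
* two wing hulls, split by 2-means on voxel coordinates, initialized at the
  two extreme voxels along the body y-axis (deterministic); identities come
  from the previous frame's wing CMs, or on the first frame from the sign
  of the projection on the approximate body y-axis (the package assumes
  body roll within +/-90 degrees at event start, or an explicit
  `forward_hint`).

## Wing geometry

The per-wing ladder refines coarse estimates into final ones:

1. **Strip**: voxels between 0.40 and 0.65 of the wing length from the body
   CM; its CM is the provisional wing CM. An empty strip triggers exactly
   one widened attempt (0.35-0.70), flagged; wing length itself is
   estimated per event as the 97.5th percentile of the farthest-voxel
   distance over the first two wingbeats.
2. **Tip and span**: provisional tip = farthest wing voxel from the body
   CM; refined tip = CM of the cone base (half-angle 30 degrees, beyond
   0.8 of the maximal radial extent) about the CM-to-tip axis.
3. **Trimmed inertia-axis refinement**: the CM-to-tip line is biased by
   several degrees because the area centroid of a wing section sits toward
   the trailing edge (the outline carries ~65% of the chord behind the
   span line), and that bias rotates with `psi`. The final span direction
   is instead the first principal axis of the wing-hull voxels after an
   iterated plane-fit trim (3 iterations, dropping voxels farther than 3
   pitches from the fitted plane). The trim also rejects occlusion ghosts
   and voxels mis-assigned from the other wing — the characteristic
   failure when the wings meet at the end of the back-stroke. If the
   inertia axis disagrees with the CM-to-tip line by more than 25 degrees
   the frame keeps the coarse estimate and is flagged.
4. **Initial chord**: 2-means on the strip voxels; the chord is the unit
   vector between cluster CMs, orthogonalized against the span, with its
   trailing-to-leading sign fixed by temporal continuity and a global
   check that the chord points, on median, along the stroke-plane normal
   (wing pitch stays inside (0, 180) degrees in normal flight).
5. **Reprojection and edges**: the wing hull is reprojected into every
   camera (rounded pixels, one morphological closing to seal rounding
   gaps); because the hull fuses all views, these masks contain pixels
   occluded by the body or the other wing in that camera. Boundary pixels
   are split into leading and trailing edges by the image line through the
   projected wing CM along the projected span; the side holding the
   projected tip velocity is the leading edge, with the label held over
   stroke reversals (tip speed below 10% of its maximum). Cameras seeing
   the wing with a projected span under 3 px or a mean projected chord
   width under 2.5 px carry no usable edge separation and are excluded.
6. **Edge hulls**: boundary pixels seen by different cameras correspond to
   different 3D wing points, so each camera's LE (or TE) pixel set is
   carved together with the *reprojected wing masks* of the other cameras
   — the same occlusion-resolving construction as the expanded hulls — and
   the results are united, restricted to a one-voxel-dilated shell of the
   wing hull. LE/TE conflicts are resolved by the chordwise coordinate.
7. **Local chords and final chord**: the span is divided into
   `n_sections` (default 5) radial bins, anchored at the outboard hull
   extent (the hull is tangency-tight at the tip, while its inboard end
   blurs into the wing-body occlusion zone). Within each bin the local
   chord connects the *tangency extremes* of the plane-trimmed wing
   voxels: the visual hull is exact where silhouette contours graze the
   object, so the voxels extreme along the current chord direction
   (within one pitch) are true outline points, while bin means — or the
   shell-dilated LE/TE label sets — would inherit the tilt of the
   asymmetric hull wedge around the thin wing. Each chord is reported at
   its *effective* station (the mean span coordinate of its extreme
   voxels; extremes cluster where the chord is widest within the bin).
   The local pitch `psi_k` is the signed rotation of each local chord
   about the span. The global chord is the support-weighted mean of the
   outer-span station chords (stations at least halfway out); root
   stations sit in the wing-body occlusion zone and are reported with
   their support counts but not trusted for the global angle.

## Body frame and kinematics

The body hull is nearly cylindrically symmetric, so only `x_b` (first
principal axis, refined by the tail-to-head blob vector, disambiguated by
temporal continuity or a first-frame flight-direction prior) can be read off
it. `y_b` comes from the wings: once per back-stroke, at the frames where
each span is most perpendicular to `x_b`, the half-difference of the left
and right spans (projected perpendicular to `x_b`) is a `y_b` sample;
samples are interpolated with a monotone cubic and re-orthogonalized per
frame; `z_b = x_b x y_b`. Angular velocities (p, q, r) come from central
differences of the orientation matrices (axis-angle of `R(t+dt) R(t-dt)^T`),
expressed in the body frame; accelerations are central differences of the
rates; series are unsmoothed by default (`smooth_rates` exists but is off).
Wingbeats are delimited at local minima of the mean stroke angle with a
minimum separation of half the nominal period, and per-beat summaries report
front/back stroke angles, their left-right difference, and wingbeat-averaged
angular accelerations.

# The synthetic fly

Because the original recordings and fly geometry are not distributable, the
package ships a fully parameterized articulated fly and renderer that stand
in for them:

* body: watertight tapered ellipsoid, length 2.5 mm, max width 1.2 mm,
  slightly fuller toward the abdomen;
* wings: planar fruit-fly-like outline, span 2.5 mm, max chord 1.0 mm with
  35% of the chord ahead of the span line, hinged 0.55 body lengths from
  the tail, offset laterally and slightly dorsally; an optional linear
  spanwise twist supports deformation-recovery experiments;
* wings carry an 80 um physical thickness so that edge-on silhouettes
  rasterize into connected masks at the default resolution (a real wing is
  thinner; the slab is symmetric about the mid-surface so chord and pitch
  estimates are unbiased);
* kinematics: harmonic waveforms — `phi` with 65-degree amplitude about a
  90-degree mean, `theta` a 10-degree figure-eight at twice the stroke
  frequency, `psi` flipping 90 +/- 50 degrees with the morphological
  leading edge leading the motion on both strokes — at 250 Hz, 73 frames
  per wingbeat, with a slowly translating (0.05 m/s) and yawing (100 deg/s)
  body pitched at 45 degrees. These values are fruit-fly-typical and fixed
  as the package's reference validation conditions.

Rendering is z-buffered triangle rasterization producing exact binary
unions, with per-part visible masks and parts-rendered-alone available so
tests know ground-truth occlusion. `voxelize_fly()` provides an *inner*
voxelization (margins of one pitch in-surface, 0.75 pitch through the wing
thickness) whose containment in every carved hull can then be asserted
exactly rather than approximately.

What the synthetic data do **not** emulate: sensor noise, motion blur,
defocus, legs and halteres, calibration error, and non-rigid chordwise
camber. Passing synthetic validation therefore demonstrates the geometric
correctness and occlusion handling of the implementation under ideal
imaging, not robustness to real-data nuisances (a 1-px mask dilation option
exists for real calibration slack and is off in all tests).

# Validation and accuracy

`validate_on_synthetic()` renders a ground-truth sequence, runs the full
pipeline on nothing but the silhouettes, removes each angle's median error
(the convention-offset compensation discussed above) and reports the SD of
the remaining errors, excluding flagged frames (their count is reported).
The reference experiment — 10 wingbeats x 73 frames on the hybrid
four-camera rig at 256 x 256 px — is what `scripts/acceptance.R` and the
acceptance tests run; at this scale the suite completes in a few minutes on
one CPU.

# Camera-configuration analysis

`wing_visibility()` scores, per camera and wing, the percentage of wing
area unoccluded and the percentage of 100 fixed outline points whose
projection is visible (nearest surface at the projected pixel within a 1-px
tolerance — the same fixed 3D points are tested in every camera).
`success_fraction()` declares a pose identifiable at a threshold when, for
both wings, the fraction of boundary points visible in at least three
cameras exceeds the threshold; curves over thresholds compare rigs. Because
the original pose ensemble is unpublished, the package ships a documented
default ensemble (uniform: yaw free, body pitch 30-60, `phi` in [-30, 160],
`theta` in [-30, 30], `psi` in [0, 180], wings independent) and treats the
rig *ordering* — hybrid4 above pyramidal4 above the three-camera rigs — as
the reproducible claim; printed percentages depend on the ensemble and are
not asserted.

# Numerical choices and degenerate inputs

* k-means calls are deterministic: explicit initial centers (extreme voxels
  along the relevant axis), no random restarts needed.
* Unit-vector post-conditions hold to 1e-9; gimbal poses (span parallel to
  the stroke-plane normal) make `phi` undefined and are flagged, holding
  the previous frame's value.
* Empty strips, empty cone bases, inseparable chord clusters, merged wings,
  and edge stages with fewer than two usable cameras all flag the frame
  rather than silently degrading; flagged frames are excluded from
  validation SDs and counted. A run with more than half its frames flagged
  is marked failed.
* Degenerate (near-spherical) body hulls fall back to the plain PCA axis
  with a warning.

# Known limitations

* Wing pitch degrades for a few frames around stroke reversals when the
  wing is chordwise edge-on to most cameras; the camera-exclusion rules
  bound, but do not remove, this error.
* The root-most spanwise stations of the deformation profile overlap the
  wing-body occlusion zone and are the least reliable; they are reported
  with their support counts so users can filter.
* Very long events re-triangulate the grid as the fly moves; hull files
  from different grid epochs share lab coordinates but not voxel indices.
* The method is silhouette-based: photo-consistency, legs, and multi-fly
  scenes are out of scope.
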