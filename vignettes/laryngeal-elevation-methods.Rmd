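---
title: "Measuring laryngeal elevation from VFSS segmentations: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring laryngeal elevation from VFSS segmentations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(laryngotrack)
```

## The measurement problem

During the swallowing reflex the larynx rises by a few centimeters in about
one second, closing the laryngeal vestibule and pulling the cricopharyngeal
sphincter open. Reduced or slowed elevation is a clinically meaningful
aspiration risk marker, but routine assessment is qualitative. A lateral
videofluoroscopic swallowing study (VFSS) records the motion at video rate
(typically 640 × 480 px, 30 fps), and instance-segmentation models can
delineate the relevant structures per frame. This package implements the
step those models do not provide: turning per-frame masks of the thyroid
cartilage + vocal fold complex (TVC) and of the C1 spinous process into a
single calibrated elevation distance, with an evaluation harness and a
synthetic data generator around it.

## Coordinate conventions and rasterization

All coordinates are image-style: `x` is the column index growing rightward,
`y` the row index growing **downward**, both 0-based; elevation therefore
corresponds to *decreasing* y. A pixel at (row r, col c) owns the center
point (c + 0.5, r + 0.5).

Polygon annotations are scan-converted by the even-odd rule evaluated at
pixel centers, with centers that fall exactly on the boundary counted as
inside. This rule is deterministic, orientation-independent, handles the
pathological case of self-intersecting contours predictably (even-odd
parity), and — crucially for testing — is checkable against an exhaustive
point-in-polygon oracle, which the test suite does for random polygons on
small canvases. Rasterization is exactly translation-equivariant for
integer shifts, which the kinematics relies on (a camera shift must not
change any measurement). Vertices outside the canvas are clipped to the
frame rectangle rather than rejected, since hand-drawn contours commonly
overshoot the border by a pixel.

## Segmentation evaluation

`iou()` is the plain pixel-count ratio |A ∩ B| / |A ∪ B|. `evaluate()`
walks every ground-truth frame and label, resolves multiple predicted
instances of a label with `match_detections()` (highest confidence score,
ties broken by larger area, then first occurrence — the resolution rule is
ours, since detectors capped at a few instances per frame can still emit
duplicates), and classifies each frame as a true positive when IoU ≥ the
cutoff.

Two parameter choices deserve comment:

* **Cutoff 0.3 (not the generic 0.5).** The downstream quantity is a
  *midpoint*, which is far more tolerant of boundary error than the mask
  itself; a loose but correctly-placed mask still yields an accurate
  centroid. The cutoff is a tunable argument (`threshold`, in (0, 1]),
  0.3 by default everywhere, including the trajectory gate. One source
  describes the gate as strictly "> 0.3" while defining TP as "≥ 0.3"; we
  use ≥ uniformly for internal consistency.
* **Missing detections in mean IoU.** A frame with ground truth but no
  prediction has no defined IoU. Recall is unaffected (it counts the frame
  as FN either way), but the mean is: the summary reports `iou_mean` with
  misses counted as 0 — the convention under which reported IoU ranges
  start at 0 — and `iou_mean_detected` excluding them, so both readings
  are available.

`compare_peak_iou()` contrasts TVC IoU at peak-elevation frames against the
remaining frames. Which frames constitute "the peak" is study-specific, so
the peak set is an explicit argument rather than something the function
infers. The test is Welch's two-sample t-test by default (no equal-variance
assumption), with Mann–Whitney U selectable; with fewer than two values per
group the means are still reported but the p-value is omitted.

`mask_bce_loss()` is the reference per-instance mask loss of two-stage
instance-segmentation networks: the mean binary cross-entropy (natural log)
over the m × m mask cells of the target's class map, m = 28 being the
conventional mask-head resolution. Probabilities are clamped to
[ε, 1 − ε], ε = 1e−7, so the loss is finite at hard 0/1 predictions; the
analytic checks (p ≡ 0.5 gives ln 2; p = y gives ≈ −ln(1 − ε)) hold to
that clamping precision. Classification and box-regression losses are out
of scope: only the mask term has package-level use as an evaluation
reference.

## Kinematics

**Midpoint.** The tracked point of a structure is the centroid of its mask
pixels' centers. The centroid moves smoothly under small boundary
perturbations, unlike, say, a topmost point; a bounding-box center mode is
available (`mode = "bbox"`) for sensitivity analysis, since "midpoint" is
not standardized in the clinical literature.

**Relative trajectory.** `rel(t) = m_TVC(t) − m_C1(t)`. The C1 spinous
process barely moves during a swallow, so referencing it cancels global
translation of the patient or the image intensifier. Frames where either
structure is undetected are marked invalid and carry missing values; we do
**not** interpolate across them — a gap in detection inside the measured
interval invalidates the event instead (see the gate), because interpolated
kinematics would silently manufacture the very quantity being measured.

**Event selection.** The swallow event is the valid-frame pair (i, j),
i < j, maximizing `rel_y(i) − rel_y(j)` — the largest upward excursion,
i.e. the longest upward trajectory of the relative midpoint. Ties go to the
smallest i, then smallest j, making the selection deterministic on plateaus
(identical rest frames before motion onset, or a held peak). If the maximum
excursion is not positive the result is an explicit `no_event` status, not
an error: a clip without a swallow is a legitimate input. The implementation
is a single running-maximum pass (O(n)); the test suite checks it against
the exhaustive O(n²) pair scan on hundreds of random trajectories.

**Gate.** A measurement is only trusted if every frame in [i, j] is valid
and — when ground truth is supplied — has TVC IoU ≥ the cutoff. Without
ground truth (the deployment case) validity alone decides. `elevation_mm()`
refuses an ungated event unless explicitly overridden, and then records
`gate_passed = FALSE` in its output.

**Calibration.** VFSS pixels are converted to millimeters with per-axis
factors `cf = known_mm / pixel_length` from reference segments of known
physical length (e.g. C3 and C4 vertebral body diagonals measured on MRI).
Two segments give independent horizontal and vertical factors; one segment
is applied isotropically. Whether a study derives one factor per axis or
averages several is a data-collection decision, so both are representable.

**Displacement.** The elevation is the calibrated Euclidean displacement of
the relative midpoint between the two event frames,
√((cf_x Δx)² + (cf_y Δy)²). A vertical-only reading cf_y·|Δy| is always
reported alongside: published elevation figures do not always state which
of the two was used, and on near-vertical trajectories they differ by well
under a percent, so reporting both costs nothing and removes the ambiguity.
Mean velocity (displacement over event duration) and peak velocity (largest
single-frame calibrated step within the event, times fps) are provided as
`elevation_velocity()`; velocity is a natural extension of the displacement
measurement and reuses the same gated interval.

## The phantom: what it emulates and what it does not

No public VFSS dataset with structure masks exists, so the package carries
a synthetic generator whose outputs are *exactly* known:

* geometry: a static C1 ellipse and a TVC ellipse, both rendered from
  64-gon contours so that every ground-truth mask has a polygon *and* a
  raster representation that agree by construction. Ellipses, not
  anatomical contours: everything downstream consumes masks and centroids,
  so shape realism contributes nothing to correctness testing;
* kinematics: the TVC center follows `y(t) = y_rest − A·g(t)` (and
  optionally `x(t) = x_rest + L·g(t)`), with `g` a raised-cosine rise over
  `rise_frames`, a plateau, and a raised-cosine fall. The profile is
  parameterized to hit 0 exactly on the first rise frame and 1 exactly on
  the last, so the true event frames are well-defined integers
  (`frame_low = 0`, `frame_peak = onset + rise − 1`);
* rendering: background intensity 30, structures 180 (0–255 scale),
  additive Gaussian noise, then Gaussian blur; all randomness from one
  seed, so identical specs produce byte-identical sequences.

Default study conditions, chosen once: 640 × 480 px at 30 fps, 60 frames,
amplitude 70 px (≈ 35 mm at the 0.5 mm/px scale used in the worked
examples — a typical elevation magnitude), rise 15 / hold 1 / fall 15
frames, i.e. ~1 s of motion at 30 fps, matching the duration of the
swallowing reflex; noise SD 10 and blur σ 1, which keep the threshold
segmenter's IoU high but not exactly 1. Motion starts at frame 0 because
clinical clips are trimmed to the reflex; a long identical-rest preamble
would also make "the" lowest-point frame ill-defined (any rest frame ties),
whereas with onset at 0 the deterministic tie-break and the truth coincide.
`hold_frames = 1` for the same reason at the top: the elevation peak is
momentary in real trajectories, and a held plateau of bit-identical frames
has no unique peak frame.

What the phantom does *not* emulate — and hence what passing tests do not
show about real data: anatomical shape and its deformation during the
swallow (the TVC contour genuinely changes shape, and its boundary contrast
drops at peak elevation, which is precisely when real segmentation quality
degrades); occlusion by the mandible or contrast bolus; multiple swallows
per clip; out-of-plane (3-D) motion components; fluoroscopic noise
statistics (quantum mottle is not Gaussian). The phantom validates the
*measurement chain*, not any segmentation model.

`degrade_mask()` manufactures predictions at a controlled IoU (±0.05) by
monotone search over a perturbation magnitude — translation distance,
dilation radius or erosion radius. Because the magnitudes are integers the
achievable IoU values are discrete; on masks that are too small relative to
the requested target the search reports the target unattainable rather than
silently returning the nearest value. The ±0.05 tolerance is part of the
function's contract and is verified by calling `iou()` on its output.

`augment_frame()` implements the standard training-time recipe — rotation
U(−30°, 30°), scale U(0.8, 1.2), per-axis shift U(−10%, 10%), horizontal
flip with p = 0.5, optional image blur — composed in the fixed order
flip → rotate → scale → shift (the order is a package choice; sources
rarely state one) into a single affine map about the image center. Images
are resampled bilinearly; masks by nearest neighbour, which keeps them
binary and makes integer shifts and flips exact set operations — properties
the test suite asserts literally.

`threshold_segmenter()` is a deliberately classical detector with the same
output contract as a learned model (per-frame labelled instances with
confidence scores): binarize at an intensity threshold (default 105, midway
between the phantom's background and structure intensities), label
8-connected components, drop components under a minimum area (default 50 px,
suppressing noise speckle), take the component whose centroid falls in a
configured C1 search box as the C1 spinous process and the largest
remaining component as the TVC. It exists so the full pipeline can be
exercised end-to-end at desk scale; any external segmentation model can be
plugged in by producing `frame_annotation` objects (or the annotation JSON)
instead.

## Numerical choices and degenerate inputs

* IoU of two empty masks is undefined and raises an error rather than
  returning a conventional value.
* Event selection requires ≥ 2 valid frames; fewer is an error at the
  function level, while the `measure` command maps it to a `no_event`
  report, since an undetectable event is an expected outcome, not a crash.
* Probability clamping in the mask loss uses ε = 1e−7 (see above).
* All stochastic operations (phantom rendering, degradation direction,
  augmentation draws) take explicit seeds and restore the caller's RNG
  state, so library use never perturbs a user's simulation stream.
* Trajectory CSV serializes numbers at full double precision; missing
  midpoints become empty fields, keeping the file loadable by any CSV
  reader without sentinel-value conventions.

## Problem sizes in the test suite

The module tests run a quarter-scale phantom (160 × 120 px, 30 frames,
30 px amplitude) so the whole suite completes in well under a minute; the
end-to-end acceptance checks use the full default phantom (640 × 480,
60 frames, 70 px) plus 1000 random mask pairs for the IoU oracle and 500
random trajectories for the event-selection oracle. These sizes were chosen
as the smallest at which every property is non-trivially exercised —
discretization error, noise, and tie-breaking all manifest — while keeping
the suite fast enough to run on every change.

## Known limitations

* Two-dimensional only: lateral-view VFSS projects 3-D motion onto a plane;
  laryngeal tilt (thyroid rotating forward while the vocal folds elevate
  less) moves the midpoint little and is invisible to this measurement.
* One swallow event per run: multi-swallow clips must be split upstream.
* No hyoid kinematics: the hyoid/airway label is carried through I/O for
  completeness but no hyoid-specific measurement is implemented.
* Calibration accuracy is bounded by the reference-segment measurement
  (e.g. MRI-derived vertebral diagonals); errors there scale the result
  linearly.
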