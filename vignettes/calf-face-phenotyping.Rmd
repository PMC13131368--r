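---
title: "Methods: keypoint evaluation and facial phenotyping in calves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: keypoint evaluation and facial phenotyping in calves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calfface)
```

`calfface` is the post-detection half of a facial-phenotyping workflow
for dairy calves. A pose-estimation network (out of scope here) places
ten facial landmarks on frames extracted from farm video at 1 frame/s;
this package evaluates how well predicted landmarks match annotated
ones, and turns landmark trajectories into welfare-related phenotypes.
This vignette documents the models, the parameters that matter, the
numerical choices, and what the synthetic validation does and does not
demonstrate.

## The 10-keypoint schema

The canonical schema names ten landmarks: `left_ear_tip`,
`left_ear_base`, `right_ear_tip`, `right_ear_base`, `left_eye_top`,
`left_eye_bottom`, `right_eye_top`, `right_eye_bottom`, `left_nostril`,
`right_nostril`. These are the minimal set supporting the traits the
package computes: ear angulation needs the ear tip, the attachment
point and a supra-ocular reference; eye opening needs landmarks above
and below each eye; nostril distance needs both nostrils. We take the
supra-ocular reference to be the same side's `eye_top` landmark — the
only landmark above the eye in a 10-point schema. All geometry operates
in pixel coordinates (origin top-left, y downward, sub-pixel values);
the COCO JSON and YOLO pose readers denormalize on input so downstream
code never sees normalized units. YOLO per-keypoint confidence is
thresholded at 0.5 (configurable) into visible/absent; COCO visibility
1 (occluded) is used for geometry but the emitted row is flagged
low-confidence, since the upstream frame filter keeps only frames with
the whole head clearly visible and occlusion should be rare.

## Keypoint accuracy: OKS, AP/AR, F1

For a predicted frame against a ground-truth frame,

$$\mathrm{OKS} \;=\; \frac{\sum_i \exp\!\big(-d_i^2 / (2 s^2 k_i^2)\big)\,\mathbf{1}[v_i>0]}
{\sum_i \mathbf{1}[v_i>0]},$$

with $d_i$ the Euclidean pixel displacement of keypoint $i$, $s^2$ the
object area (bbox width × height when a bbox exists, else the bounding
box of the visible truth keypoints), $k_i$ a per-keypoint constant and
$v_i$ the truth visibility. Properties that the tests verify: OKS is 1
at zero displacement, invariant to joint translation and to uniform
rescaling of coordinates and $\sqrt{\text{area}}$, and strictly
decreasing in any single keypoint's displacement.

Two choices were genuinely open:

- **Per-keypoint constants $k_i$.** No calf-face constants exist in the
  literature. We default to a uniform $k_i = 0.05$ — the magnitude used
  for fine facial keypoints in the human-pose OKS tradition — and keep
  them configurable per label. Uniform constants keep all ten landmarks
  exchangeable, which also makes the evaluation invariant to label
  order.
- **Matching protocol.** The video-splitting step upstream yields one
  calf per frame, so evaluation assumes one scored prediction per truth
  instance. At each threshold $\tau$ of the sweep
  $\{0.50, 0.55, \dots, 0.95\}$, a score within the threshold
  ($\mathrm{OKS} \ge \tau$, ties inclusive) is a true positive and
  below it a false positive; precision is tp/(tp+fp) and recall
  tp/(number of truth instances), so with no missed detections the two
  coincide per threshold while missed truths (supported through
  `n_truth`) depress recall only. AP and AR are arithmetic means over
  the ten thresholds, and F1 is the harmonic mean of AP and AR. Under
  this rule precision is necessarily non-increasing in $\tau$; a
  reported AP at 0.95 exceeding AP at 0.75 cannot arise from it, which
  is why trained-model metric tables from specific studies are not
  reproduction targets for this package.

## Geometric traits

The ear angle is computed at the ear attachment (base) landmark — the
hinge of ear rotation and the only "head" landmark among the three —
by the law of cosines with legs $a = |\mathrm{base}-\mathrm{tip}|$,
$c = |\mathrm{base}-\mathrm{eye}|$ and opposite side
$b = |\mathrm{tip}-\mathrm{eye}|$:
$\cos\theta = (a^2 + c^2 - b^2)/(2ac)$. The cosine is clamped to
$[-1, 1]$ before the arccosine, and configurations with any pairwise
distance below $\varepsilon = 10^{-6}$ px raise a degeneracy error
naming the offending pair. An angle above 90° classifies the ear as
backward; 90° exactly is frontward. The tests check the law-of-cosines
route against an independent dot-product/arccos oracle to $10^{-6}$
degrees on random triangles, and that mirroring a frame's
x-coordinates swaps left and right traits exactly.

Distances are converted to centimeters by the ear-tag fiducial:
`cm_per_px = tag_size_cm / tag_extent_px`, the extent being the tag's
larger pixel dimension. No universal tag standard exists; the physical
size is a required input (the synthetic default is 7.0 cm, a typical
cattle-tag width). Calibration is per sequence here because the
generator renders at constant scale; with real video whose scale
drifts, a per-frame tag extent can be supplied frame by frame. Head
yaw is not corrected: like the underlying field protocol, distances
are measured in the image plane and are therefore influenced by head
pose and size — a stated limitation, not a bug.

An absent keypoint (visibility 0) yields a missing trait value, never
an exception; skipped frames are counted in the pipeline run log.

## Temporal traits

Each frame with a defined posture contributes $1/\text{frame rate}$
seconds to that posture's time budget, so front + back time equals the
defined-frame count over the frame rate (a conservation law in the
tests). Ear movements — transitions between frontward and backward in
consecutive frames — are quantified only where at least 20 consecutive
defined frames are available (20 s at 1 fps). Three choices:

- **Windowing.** Whether counts are per 20-frame window or per whole
  run is ambiguous in the field description; we count per
  non-overlapping ("tumbling") 20-frame window from the start of each
  maximal run, which never double-counts a transition, and expose a
  sliding mode for sensitivity analyses. Trailing partial windows are
  dropped.
- **Gaps.** Missing postures break runs; positions on the two sides of
  a gap are never compared, so a gap can never manufacture a
  transition. Interpolating across gaps would invent behavior.
- **Pooling.** Budgets and counts are computed per ear; the
  descriptive summary pools both ears' windows into the single
  ear-movement row, matching how such tables are reported.

## The synthetic generator

`simulate_trajectory()` emulates what the study population's data look
like after detection, with known ground truth. A fixed head template
in cm places the nostrils 5.93 cm apart and the eyelid landmarks
2.75 cm (left) and 2.76 cm (right) apart — the descriptive means of
the motivating study population — with ear bases 6 cm lateral of the
midline and a 7 cm ear. Each ear's posture follows its own two-state
Markov chain; the per-frame angle is the state mean (60° front, 120°
back by default) plus Gaussian jitter (SD 5°), and the tip is rotated
about the base so the tip–base–eye angle equals that value exactly.
The template is scaled (12 px/cm default, i.e. a head roughly 190 px
wide on a 640 px frame), translated to the image center with 2 px of
global jitter, and perturbed with isotropic Gaussian keypoint noise
(SD 1 px default). The ear-tag extent is emitted as
`tag_size_cm × scale_px_per_cm` so calibration recovers the true scale
exactly.

The chain defaults were set once from the study population's
aggregates: a stationary frontward fraction of
$9.72/(9.72+5.43) = 0.642$ and a mean switch rate of $3.73/19 = 0.196$
per frame-pair give $p_{\text{front}\to\text{back}} = 0.153$ and
$p_{\text{back}\to\text{front}} = 0.274$. These are plausibility
settings, not estimates — the aggregates constrain only two moments of
the behavior. For a two-state chain the expected transitions per
20-frame window is $19\,p_{\text{switch}}$ with
$p_{\text{switch}} = \pi_F p_{FB} + \pi_B p_{BF}$, the closed form the
transition counter is validated against within Monte-Carlo error.

What passing the synthetic suite does **not** show about real data:
the generator has no head yaw or foreshortening, no camera shake
beyond translation jitter, no correlated (systematic) detector error,
no occlusion structure, and its noise is homoscedastic across
landmarks. It validates the estimators' correctness, not detector
robustness.

## Dataset handling and summaries

`holdout_count()` rounds `total × fraction` to the nearest image
(6,702 images at 10% → 670 train, 6,032 predict).
`group_split()` assigns whole animals to train/val/test so image
proportions approximate the targets (animals shuffled by seed, then
greedy largest-deficit assignment with each subset seeded by one
animal); no animal — hence no image — ever spans subsets.
`summarize_trait()` reports min, mean, max, sample SD (n−1 denominator,
the norm for "± SD" reporting) and CV = 100·SD/mean, displayed to the
nearest integer percent. CV is computed before any display rounding;
reconstructing integer CVs from already-rounded means and SDs can
disagree by one point with CVs computed on unrounded data, so only
rows consistent under nearest-integer rounding are used as exact
checks.

## Problem sizes and determinism

The validation suite uses 1,000–10,000 random instances for the
algebraic oracles and a single 5,000-frame trajectory (≈ 250 windows
per ear) for parameter recovery — enough for the 2% recovery tolerance
and 3-SE Monte-Carlo bands to be meaningful while keeping the whole
suite under a minute of compute. All randomness flows through explicit
seeds; the generator saves and restores the caller's RNG state, and
pipeline outputs are a pure function of inputs, configuration and
seed (re-runs are byte-identical).
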