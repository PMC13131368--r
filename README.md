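# calfface

Facial phenotyping of dairy calves from detected keypoints.

Pose-estimation networks can locate facial landmarks (ear tips and
attachment points, eyelids, nostrils) on calf images, and those landmarks
carry welfare information: ear posture and movement, eye opening and
nostril distance are established indicators of arousal, pain and stress
in cattle. `calfface` implements everything that happens *after*
detection, for researchers in precision livestock farming and animal
welfare:

- **Keypoint-accuracy evaluation.** Object keypoint similarity between a
  predicted and a true 10-keypoint frame,

  OKS = Σᵢ exp(−dᵢ² / (2 s² kᵢ²)) · 1[vᵢ > 0] / Σᵢ 1[vᵢ > 0],

  with dᵢ the Euclidean pixel displacement of keypoint *i*, s² the object
  area in pixels, kᵢ a per-keypoint falloff constant and vᵢ the
  ground-truth visibility. Scores are swept over thresholds
  τ ∈ {0.50, 0.55, …, 0.95}; a prediction within the threshold
  (OKS ≥ τ) is a true positive, below it a false positive. AP and AR are
  the sweep means of per-threshold precision and recall, and
  F1 = 2PR/(P+R).
- **Geometric traits.** The ear angle θ at the ear attachment landmark is
  computed by the law of cosines from the ear tip, ear base and the
  supra-ocular (upper eyelid) landmark; θ > 90° classifies the ear as
  backward, θ ≤ 90° as frontward. Eye opening and nostril distance are
  Euclidean distances converted from pixels to centimeters by the known
  physical size of the animal's ear tag.
- **Temporal traits.** Per-ear time in each posture from the frame rate,
  and ear movements (posture transitions between consecutive frames)
  counted only within runs of ≥ 20 consecutive defined frames (20 s at
  1 frame/s).
- **Dataset handling and summaries.** Animal-grouped train/val/test
  splitting that prevents identity leakage, train-vs-predict holdout
  arithmetic, and min/mean/max/SD/CV descriptive tables of the extracted
  traits.
- **A synthetic generator.** Real farm videos of this kind are rarely
  deposited, so `simulate_trajectory()` emits 10-keypoint calf-face
  trajectories with known ground truth: a fixed head template in cm, ears
  driven by a two-state (front/back) Markov chain with angular jitter,
  Gaussian keypoint noise and an ear-tag fiducial of known size. Every
  stage of the package is validated against it.

## Worked example

```r
library(calfface)

# simulate a 500-frame session and corrupt the keypoints by 2 px
sim   <- simulate_trajectory(head_model_params(n_frames = 500L, seed = 201))
pred  <- corrupt_keypoints(sim$trajectory, displacement_sd_px = 2, seed = 202)
pairs <- lapply(seq_len(500), function(i)
  list(pred = pred$frames[[i]], truth = sim$trajectory$frames[[i]]))
evaluate_keypoints(pairs)
#> <oks_eval> 500 instances | AP 0.95 AR 0.95 F1 0.95

# phenotype the true trajectory, calibrated by the 7 cm ear tag
cal <- scale_calibration(7, sim$tag_extent_px)
session_phenotypes(sim$trajectory, cal)[, c(
  "nostril_distance_cm", "eye_opening_left_cm", "ear_movement_count")]
```

With 2 px of keypoint noise the synthetic "detector" reaches mean
OKS 0.948 and AP = AR = F1 ≈ 0.95 — accuracy in the range reported for
well-trained pose models — and the recovered nostril distance (5.9300 cm
here; 5.926–5.931 cm across the `analysis/` sessions) matches the
generator's 5.93 cm setting. The ear-movement count is the mean number of
posture transitions per qualifying 20-frame window (3.3–4.0 under the
default dynamics).

The `analysis/` directory holds the narrative drivers, to be run from the
repository root in order:

```sh
Rscript analysis/01_simulate.R       # synthetic sessions -> results/sim/
Rscript analysis/02_evaluate_oks.R   # OKS sweep vs noise -> results/oks_by_noise.csv
Rscript analysis/03_phenotypes.R     # traits + summaries -> results/phenotypes.csv, summary.csv
Rscript analysis/04_dataset_split.R  # holdout + grouped split -> results/split.csv
```

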