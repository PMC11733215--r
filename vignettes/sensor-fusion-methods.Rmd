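---
title: "Multimodal classification of infant fidgety movements: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal classification of infant fidgety movements: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

The general movement assessment (GMA) evaluates the quality of an
infant's spontaneous movements to screen for neurological impairment in
the first months of life. Around 3 months post-term, the key
age-specific pattern is the *fidgety movement* (FM): small-amplitude,
moderate-frequency movements of the limbs, neck and trunk. `fmfusion`
classifies 5-second recording units ("snippets") as FM+ (fidgety
movements present) or FM- (absent) from three synchronized sensor
modalities, and quantifies whether fusing modalities beats any single
one:

* **VID** — 15 2D pose key points per frame at 50 Hz (250 frames),
  in pixels, as produced by a pose estimator from video;
* **MAT** — a 32 x 32 pressure image at 100 Hz (500 frames) from a
  pressure-sensing mat under the infant;
* **IMU** — six inertial units (shoulders, hips, feet), each with a
  3-axis accelerometer and 3-axis gyroscope, at 60 Hz (300 frames).

Labels are binary: FM- = 0, FM+ = 1; not-assessable snippets are
excluded, as are snippets missing any required modality
(`filter_synchronized()`).

## Feature extraction

### Video (250 x 60)

Each of the 30 coordinate series is passed through a median filter and
then a moving-average filter, both with a 5-frame centered window
(truncated at the series boundaries, so no data is invented). The
median stage absorbs isolated pose-estimation outliers; no separate
outlier detector is used.

The skeleton is then normalized per snippet:

1. **Centering**: the across-frames average midpoint of the two hip
   key points is subtracted from every key point of every frame.
2. **Rotation**: all frames are rotated by the signed angle
   `atan2(x, y)` of the across-frames average shoulder midpoint, which
   places the trunk midline exactly on the +Y axis. The signed angle
   matters: an unsigned `acos` of the normalized dot product would send
   left-tilted skeletons to -Y.
3. **Scaling**: all coordinates are divided by three times the
   vertical hip-to-shoulder distance, fixing the trunk length at 1/3.

Each key-point series is then mean-centered within the snippet,
velocities are added as central finite differences (forward/backward
at the edge frames; the constant frame-rate factor is absorbed by the
subsequent z-scoring), and positions and velocities are z-scored
*separately* with pooled statistics — one mean/sd over every position
value (all key points, both axes, all training snippets) and one over
every velocity value — fitted on the training side of each fold only
and frozen for the test side. The result is 250 x 60, columns ordered
`x1_p, y1_p, ..., x15_p, y15_p, x1_v, y1_v, ..., x15_v, y15_v`.
Key-point accelerations can be appended (`include_acceleration`,
250 x 90) for ablation studies; they are off by default.

The whole pipeline is invariant to translation, rotation and uniform
scaling of the raw pixel coordinates. One subtlety: the median filter
commutes exactly with rotations only where trajectories are locally
monotone; with smooth motion the residual discrepancy is negligible,
and the package's sharp invariance test uses linear-motion fixtures
where commutation is exact.

### Pressure mat (500 x 6)

Frames are cropped to the 29 x 26 active area (rows 1-29, columns
4-29, 1-based inclusive — the only reading consistent with 754
retained sensors), split into a top 12 x 26 region (shoulders/head)
and a bottom 17 x 26 region (hips). Per frame and region we compute
the center of pressure — the pressure-weighted mean column (x) and row
(y) index — and the mean pressure over the *fixed* region size
(m x n cells, regardless of how many are active). The six series are
smoothed (moving average, window 5) and normalized to [0, 1] per
snippet with shared denominators: the four coordinate series share
`gamma`, the largest of their ranges; the two pressure series share
`beta`. Sharing the denominator preserves relative amplitudes across
regions while removing body-size and weight effects.

Frames with zero total pressure in a region (possible in synthetic or
edge data; the centroid is undefined there) carry the last valid CoP
forward, falling back to the region centroid if none exists; such
events are counted and logged when `options(fmfusion.verbose = TRUE)`.

### IMU (300 x 36)

Each of the 36 channel series (sensor-major:
ax, ay, az, gx, gy, gz for L-shoulder, R-shoulder, L-hip, R-hip,
L-foot, R-foot) is smoothed (moving average, window 5 — no median
stage here; wearable channels do not exhibit the isolated-spike
failure mode of pose estimation) and mean-centered per series, which
removes the constant gravity component from the accelerometers.
Accelerations and angular velocities are then z-scored separately with
pooled training statistics, making the pipeline agnostic to the
physical units of either channel group. No resampling happens here;
IMU features stay at 60 Hz.

## Classifier

All models use one compact 1-D temporal CNN: three convolution blocks
(Conv1D over the frame axis, feature columns as channels, stride 1,
same padding, no pooling) and one fully connected block, each block
being Conv/Dense -> BatchNorm -> ReLU -> Dropout(0.20), then a single
linear output unit. The loss is binary cross-entropy on the logit;
the optimizer is Adam (batch size 4, learning rate 0.001, beta1 0.9,
beta2 0.999, epsilon 1e-07). Training holds out the last 1/8 of a
seeded snippet-level shuffle for validation and stops when the
validation loss has not improved for 10 epochs; the weights of the
best validation epoch are kept. Each model is trained `n_restarts`
times from independent initializations and the restart with the lowest
validation loss is selected (the full protocol uses 20 restarts;
desk-scale runs here use 3).

Design choices worth stating explicitly:

* Block order is Conv -> BN -> ReLU -> Dropout (the conventional
  reading of "each layer followed by batch normalization and
  dropout" with ReLU activations).
* BatchNorm uses batch statistics in training (momentum 0.99 running
  updates; epsilon 1e-3) and running statistics at inference; dropout
  is inverted and disabled at inference, so prediction is
  deterministic.
* The validation split is snippet-level, not infant-level: the split
  guards overfitting during optimization, while infant-level
  disjointness is enforced where it matters scientifically — between
  training and test folds.
* Class imbalance is left untouched (no reweighting); balanced
  accuracy is the headline metric.
* Initialization is Glorot-uniform; all randomness (initialization,
  shuffling, dropout) flows from one 64-bit counter-based generator
  seeded explicitly, so training is bit-wise reproducible.
* The default architecture is 32/64/64 kernels of width 5 with a
  64-unit FC layer (`cnn_config()`); desk-scale experiments use
  8/8/8 kernels and 16 FC units (`cnn_config_small()`), which is
  ample for the synthetic cohorts. Interior hyperparameters are fully
  configurable, and `grid_search_light()` provides a reduced grid
  search ranked by validation loss.

The CNN is implemented from scratch in RcppArmadillo (forward,
backward, Adam, early stopping); mini-batches are stacked along the
frame axis so each layer is a single GEMM, with per-sample padding so
convolutions never mix adjacent snippets.

## Sensor fusion

* **Late fusion**: each modality's network emits the FM+ probability
  (sigmoid of its logit); the arithmetic mean of the 2-3 probabilities
  is thresholded at 0.5. Probabilities, not logits, are averaged, and
  the tie `p = 0.5` classifies FM+ (ties are measure-zero but must be
  defined).
* **Early fusion**: MAT and IMU feature matrices are down-sampled to
  the 250-frame video grid by per-column linear interpolation onto a
  uniform grid (endpoints preserved exactly; the upstream
  moving-average smoothing already suppresses the frequencies that
  naive down-sampling could alias), then concatenated in the fixed
  order MAT(6) + IMU(36) + VID(60) = 102 channels, and classified by
  one network.

## Evaluation protocol

36 infants are partitioned (seeded) into 9 disjoint subsets of 4;
fold f tests on subset f and trains on the other 32 infants, so no
infant contributes to both sides. Per fold and model we accumulate
confusion counts and report sensitivity TPR = TP/(TP+FN), specificity
TNR = TN/(TN+FP), and balanced accuracy BA = (TPR+TNR)/2, with means
and Student-t 95% confidence intervals over the 9 folds (t, not
normal, because n = 9). Folds whose test set lacks a class are
reported metric-undefined and excluded from the means.

Models are compared pairwise on per-fold BA with the two-sided
Wilcoxon signed-rank test: zero differences dropped (Wilcoxon's
original treatment; Pratt's variant would change p on tied folds),
mid-ranks for ties, exact enumeration of all 2^m sign assignments for
m <= 15 (with n = 9 tie-free folds the attainable two-sided p-values
form the lattice 2k/512, whose extremes 2/512 = 0.0039 and
4/512 = 0.0078 the tests pin down), and a tie-corrected,
continuity-corrected normal approximation above. Cohen's kappa is
provided for interrater-agreement analyses of annotation data.

Normalization statistics are refitted inside every fold on its
training snippets only — the leakage-safe protocol — and per-fold,
per-restart training seeds are derived deterministically from the
master seed, so an entire cross-validation reproduces bit-wise.

## The synthetic cohort generator

`generate_dataset()` emulates the recording setup so the whole
pipeline is testable without access to recorded infants. Latent limb
and trunk displacement trajectories are sums of random-phase
sinusoids: a baseline component in 0.1-0.5 Hz with ~40 px amplitude
(both classes), plus — for FM+ snippets only — a smaller "fidgety"
component in 1-3 Hz (default 18 px), concentrated on the distal limb
channels, with a reduced share on elbows/knees and trunk. The latents
are rendered to all three modalities: key points on a canonical
supine skeleton (y-up pixel convention) with Gaussian jitter and
sparse outlier spikes; two Gaussian pressure blobs whose centers track
the shoulder and hip midpoints (the bottom blob also follows the
ankles) discretized to the 32 x 32 grid, clipped at zero; and IMU
channels as second finite differences of the attached body point
(times rate squared, plus a constant per-sensor gravity offset that
per-series centering must remove) and first differences of segment
angles, plus channel noise. Per-infant amplitude effects are
log-normal; labels are i.i.d. Bernoulli(0.56), matching the observed
FM+ prevalence; modalities can be deleted independently at a
configurable rate to exercise the synchronization filter. One master
seed drives everything through per-snippet substreams, so any subset
regenerates identically.

With `split_signal = TRUE` the generator draws three mutually
independent fidgety components and expresses exactly one in each
modality. Each modality then carries a weak, independent class signal
— the regime where probability-averaging fusion should beat every
single modality. Because finite differencing amplifies the 1-3 Hz
band by (2 pi f)^2, an unattenuated IMU component would dominate the
other modalities; the IMU-expressed component is therefore scaled by
a fixed 0.12 in split mode so all three signals are comparably weak.

What the generator does *not* emulate: biomechanically valid infant
kinematics, pose-estimation failure modes beyond isolated spikes,
drift or non-stationarity within a snippet, mat contact nonlinearity,
or IMU orientation dynamics (gravity is constant per sensor within a
snippet). Passing tests on synthetic cohorts therefore demonstrate
that the pipeline's mechanics — feature equations, leakage-free
protocol, fusion logic, statistics — are correct and that the
classifier can exploit band-limited class differences; they do not
certify clinical accuracy on recorded data.

## Desk-scale study conditions

Cross-validation experiments in the tests and the acceptance script
use cohorts of 36 infants x 20 snippets (1683 snippets from 36
cross-validation infants in the recorded study; 720 here keeps a
single-CPU run in minutes), the small CNN, 3 restarts, and a 10-epoch
cap (with patience 10; on these separable cohorts validation loss
plateaus within a few epochs). Three cohorts are used:

* a **strong-signal** cohort (`fidgety_amp = 40`, shared across
  modalities) on which every single modality should classify well;
* a **split-signal** cohort (`fidgety_amp = 12`,
  `split_signal = TRUE`) on which three-way late fusion should beat
  the best single modality;
* a **no-signal** control (`fidgety_amp = 0`) on which balanced
  accuracy should sit in the 95% binomial band around chance.

## Numerical choices and degenerate inputs

* Pooled z-scores use the population (divide-by-N) standard
  deviation, so normalizing a training pool by its own statistics
  yields exactly mean 0, sd 1; a zero-variance pool is an error.
* Smoothing windows must be odd; boundary windows truncate.
* `gamma = 0` (no CoP motion at all) and `beta = 0` (constant
  pressure in both regions) are degenerate-input errors rather than
  silent division by zero.
* A skeleton whose shoulder center coincides with the origin, or with
  zero hip-shoulder distance, is a degenerate-geometry error.
* Wilcoxon with all differences zero is test-undefined; kappa with
  chance agreement 1 is undefined.
* All on-disk numbers are written as `%.17g` text, so dataset
  round-trips are bit-exact.

## Known limitations

The synthetic generator is a mechanism check, not a clinical
benchmark; accuracies on it say nothing quantitative about recorded
infant data. The full two-stage hyperparameter search of the original
protocol (Bayesian optimization plus large grids) is out of scope —
`grid_search_light()` covers the reduced fine-tuning stage only. The
package consumes extracted key points; pose estimation itself, video
decoding, and recording-hardware synchronization are out of scope.
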