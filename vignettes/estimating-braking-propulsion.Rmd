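---
title: "Estimating braking and propulsion forces from wearable inertial sensors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating braking and propulsion forces from wearable inertial sensors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(runkinetics)
```

## The problem

The anterior-posterior component of the ground reaction force (AP-GRF)
during running decomposes into a braking phase (negative, anterior) and a
propulsion phase (positive, posterior). Both carry information about
performance and injury risk, but they are measured with force plates —
instruments confined to laboratories. Body-worn inertial measurement units
(IMUs) can be worn anywhere; the question is whether a regression model
trained on lab treadmill data, where IMU and force-plate recordings are
synchronized, can estimate braking and propulsion forces during overground
running, and how much individual data it takes to adapt such a model to a
new runner and a new setting.

`runkinetics` implements that pipeline end to end: signal conditioning,
stance segmentation, a bidirectional LSTM sequence regressor with
generalized training and individual fine-tuning, leave-one-runner-out
evaluation, and an impulse-versus-speed validation usable where no force
plates exist. Because no public dataset accompanies the problem, the
package ships a synthetic gait simulator with known ground truth, so every
stage is testable.

## The estimation model

The regressor maps a 22-frame window of sensor channels (four IMUs —
pelvis, left thigh, shank, foot — each with tri-axial acceleration and
angular velocity, plus sagittal segment angles for thigh, shank and foot;
27 channels in total at 120 Hz) to the AP-GRF, in percent bodyweight
(%BW), at the window's mid-point frame. Architecture: two bidirectional
LSTM layers of 64 units per direction, dropout 0.2 on the mid-point
read-out, dense layers of 128 and 64 ReLU units, scalar output. Training
uses the smooth-L1 loss (transition point 1), AdamW (learning rate 0.001,
weight decay 0.01). Continuous waveforms are produced by sliding the
window one frame at a time and stitching the mid-point predictions.

Three training modes mirror how such a model reaches a new runner:

* **Generalized** (`train_generalized()`): trained on treadmill stances of
  many runners (40 epochs, batch 32, 9:1 random stance-level
  train:validation split).
* **Fine-tuned** (`fine_tune()`): all weights of a generalized model
  updated on a handful of the target runner's stances (15 epochs, batch
  16, a 4-stance validation set).
* **Individual** (`train_individual()`): the same small stance set, fresh
  initialisation, batch 1.

Design choices the architecture description leaves open, and how this
package resolves them:

* The bidirectional recurrent output is read **at the mid-point
  timestep** and fed to the dense head. The alternative — concatenating
  final states of both directions — was rejected for symmetry with the
  mid-point target: both directions then see context balanced around the
  predicted frame.
* Dense activations are ReLU; smooth-L1 transition `beta = 1`; AdamW
  weight decay 0.01. All recorded in the estimator's provenance.
* Targets stay in raw %BW rather than being min-max normalised: reported
  errors are in %BW and the swing-phase target is exactly zero, which the
  swing-detection rule depends on.
* Model selection keeps the epoch with the lowest validation loss
  (`pick_best = TRUE`); the final-epoch model is a configuration flag
  away.
* Training may subsample sub-sequences with a stride
  (`train_config(subseq_stride = )`) to trade training-set density for
  time; inference always uses hop 1. The stride is recorded in
  provenance.
* Fine-tuning keeps the pre-trained normalisation (the weights were
  learned under it); individual models fit their own.

The LSTM, backpropagation through time, and AdamW are implemented in
RcppArmadillo inside the package; every random draw (initialisation,
shuffling, dropout) goes through R's RNG so a single seed reproduces a
training run bit-exactly. The analytic gradients are checked against
finite differences in the test suite.

## Signal conditioning

* **Filtering**: zero-phase (forward-backward) fourth-order Butterworth
  low-pass at 50 Hz for all channels. The series is extended by odd
  reflection over `3 * (order + 1)` samples and each pass starts from
  steady-state initial conditions, so constants pass through exactly and
  time-symmetric inputs stay symmetric.
* **Force resampling**: force plates sample at 2 kHz, the IMUs at 120 Hz.
  Since the force is already low-passed at 50 Hz (below the 60 Hz IMU
  Nyquist), interpolation onto IMU timestamps is alias-safe; a cubic
  spline keeps the interpolation error orders of magnitude below sensor
  noise, where linear interpolation would leave a ~1e-4 relative ripple.
* **Normalisation**: grouped min-max learned from training data only. One
  `(min, max)` pair per (sensor, modality) triplet of axes — so relative
  magnitudes within a sensor are preserved — and one per angle channel.
  The wording "across all dimensions in the training set" could also be
  read as one global group over all sensors; the per-sensor reading was
  chosen because it preserves each sensor's internal geometry while not
  letting a hot sensor (foot accelerations) flatten a quiet one (pelvis).
  Test-set values outside the training range map outside [0, 1], never
  clipped.
* **Sagittal angles**: complementary filter fusing the medio-lateral
  gyroscope with the accelerometer inclination `atan2(acc_x, acc_z)`
  (`alpha = 0.998`, crossover about 0.04 Hz), which removes gyro
  integration drift while keeping within-stride dynamics.
* **Synchronisation**: integer-lag normalised cross-correlation between a
  reference angle trace and the IMU-derived angle.

## Segmentation

Stances for training come from the vertical force: a stance is a maximal
run of frames above 20 N, initial contact (IC) its first frame, toe off
(TO) the first frame after it (1-based frame indices throughout). Each
stance is extended by 29 frames (0.242 s) of swing context per side;
windows clipped by the series bounds are flagged and excluded from
training by default.

At inference no force exists, so gait events come from the predictions
themselves: a swing is a run of at least 5 consecutive frames with
magnitude at most 0.5 %BW and within-run frame-to-frame steps of at most
0.25 %BW (the step into the run's first frame is exempt — this is the
reading under which an abrupt landing after a flat swing still begins the
swing at its first quiet frame). Runs shorter than 5 frames (about 40 ms)
are ignored; stances are the intervals between consecutive swings, and
inter-swing slivers shorter than 0.1 s are discarded. Evaluation RMSE is
restricted to stance frames so that trivially-correct swing predictions
(~0 %BW) cannot dilute the error.

## Impulse-speed validation

Where no force plate exists, predictions are validated through physics:
braking and propulsion impulses (time integrals of the negative and
positive AP-GRF portions over a stance, %BW·s) vary linearly with running
speed. Stances are binned into 25 half-open 0.1 m/s speed bins over
[2, 4.5) m/s; bins with fewer than three stances are discarded; a linear
model of impulse on speed is fitted to the surviving bins' individual
stances with inverse-variance weights `w_i = 1 / var_i` per bin
(degenerate bins floored at `1e-8`). Two fitted lines are compared by
their RMSE over the 25 bin centres (2.05, 2.15, …, 4.45 m/s) — this
reconciles "25 points" with a range whose 0.1 m/s edge grid would have
26. The fit regresses the individual member observations, not bin means;
with equal weights it reduces exactly to ordinary least squares (a test
asserts this).

Impulses are integrated with composite Simpson quadrature rather than a
plain trapezoid: at 120 Hz a trapezoid biases a 0.05 s half-sine lobe by
about −2.3 %, beyond the 1 % accuracy the package promises across
realistic lobe durations (0.05–0.2 s).

## The synthetic gait simulator

The simulator emulates the statistical structure the pipeline assumes,
with known truth:

* **Runners** (`generate_runner()`): mass ~ N(72.8, 14.2) kg (clipped to
  [50, 105]), cadence uniform in [162, 182] steps/min, duty factor
  (stance fraction of the stride) uniform in [0.30, 0.40], braking and
  propulsion gains ~ N(6.5, 0.8) and N(7.0, 0.8) %BW per m/s, per-channel
  style factors (log-normal, sd 0.08) and per-modality noise levels. The
  anthropometrics follow a recreational-runner cohort; the gains put peak
  AP-GRF near ±20 %BW at 3 m/s, typical of level running.
* **Force**: each stance's AP-GRF is a negative half-sine braking lobe
  over the first 45 % of stance followed by a positive half-sine
  propulsion lobe — fixed, documented lobe timing, chosen as the simplest
  shape with the right impulse structure. Amplitudes are `gain × speed`,
  with 3 % step-to-step variability, so per-stance impulses are linear in
  speed by construction. Vertical force is a half-sine peaking at 2.4
  bodyweights and is what the 20 N threshold sees.
* **Sensors**: segment angles are speed-scaled sinusoids of gait phase;
  the medio-lateral gyro is the sampled angle's central difference (so
  gyro and angle are kinematically consistent — the property the angle
  extraction test relies on); accelerometers see gravity through the
  segment angle plus zero-mean motion transients: an impact wavelet at IC
  whose amplitude carries the braking gain, and a late-stance push wavelet
  whose amplitude carries the propulsion gain. Speed-amplitude scaling is
  smoothed over about a third of a second so commanded speed changes do
  not create kinematic discontinuities. Gaussian noise per channel.
* **Settings**: treadmill (TM) is the identity. Overground (OG) multiplies
  the propulsion force amplitude by 1.2 and shifts the foot angle by −5°
  at contact; outdoor (OUT) adds extra sensor noise and withholds force
  truth from the pipeline (tests may read it). Crucially, the propulsion
  shift acts on the *force only* — the inertial signals do not encode it —
  so a treadmill-trained model is systematically biased overground and
  only individual overground data can correct it. That is precisely the
  transfer gap fine-tuning is meant to close, now as a controlled
  variable: setting `propulsion_shift = 1` removes the gap, a knob no
  human study has.
* **Speeds**: piecewise-constant schedules within [2, 4.5] m/s (treadmill
  2.4–3.6, overground 2.5–3.7, outdoor 2.5–3.9 by default) with small
  per-stride jitter, emulating the increase/decrease-every-interval
  protocol and populating the validation speed bins.

What the simulator does **not** model: soft-tissue artefacts, sensor
drift and re-donning variation, surface stiffness and air resistance,
curved-path running, bilateral asymmetry, foot-strike-type diversity, and
the full nonlinearity of real IMU-to-force relationships. Passing tests
therefore demonstrate that the pipeline's machinery is correct and that
its comparisons point the right way under a controlled domain shift — not
that a particular accuracy will be reached on real runners.

## Study conditions used by the tests and the reproduction script

`run_transfer_study()` re-enacts the whole design at a desk scale chosen
to keep a full run in the tens of minutes on one core: 6 runners,
treadmill sessions of 105 s (~150 stances each), overground and outdoor
sessions of 60 s (~85 stances, split chronologically into a fine-tuning
pool and a held-back test half), generalized training for 4 epochs with
sub-sequence stride 4, fine-tuning for 15 epochs (stride 2, k = 8 strides
plus a fixed 4-stance validation set anchored after the largest swept k),
individual training for 10 epochs, and three training seeds for every
stochastic comparison, reported as means. Five runners carry outdoor
sessions for the impulse-speed validation. The full-scale configuration
(40 generalized epochs, hop-1 training, 15 runners) is the package
default in `train_config()`; the scaled run reproduces the qualitative
structure — transfer, the benefit of fine-tuning, the stride-count trend,
and the validation direction — not any particular error magnitude.

## Numerical and degenerate-input policy

* Frame indices are 1-based; the sub-sequence mid-point of a 22-frame
  window is local frame 12.
* Too-short series (filtering below `3 * 3 * (order + 1)` samples,
  sessions shorter than 22 frames, sub-sequences from fewer than 22
  frames) raise errors rather than degrade.
* Degenerate normalisation groups (max = min), empty training sets,
  single-runner generalized training, overlapping train/test stances
  (checked via stance fingerprints), and validation with fewer than two
  surviving speed bins all raise structured errors.
* Stances touching the series ends are dropped as incomplete; windows
  clipped by the bounds are flagged.
* Event matching in `event_rmse()` pairs each predicted event with the
  nearest reference event and drops pairs farther than half the median
  stride period, reporting them as unmatched instead of letting outliers
  dominate.

## Known limitations

The estimator's accuracy figures on synthetic data say nothing
quantitative about real IMU data. Individual training at batch size 1 is
slow and, at the scaled epoch budget, far from converged — its role here
is the ordering comparison against fine-tuning. The complementary-filter
angle extraction assumes predominantly sagittal motion and a consistent
accelerometer; it is not a general orientation estimator. The swing rule
assumes predictions near zero during swing; a model that has not learned
that property will produce spurious stances, which the minimum-duration
guard only partially filters.
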