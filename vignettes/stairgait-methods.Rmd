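---
title: "Methods: synthetic stair-ascent cohorts and the wearable-ANN workflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic stair-ascent cohorts and the wearable-ANN workflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stairgait)
```

## What this package models

During stair ascent, the hip moves through a large sagittal arc and a
smaller frontal arc while hip moments alternate between extensor and flexor
action, with a double abductor burst during stance. The wearable workflow
estimates the four curves — sagittal/frontal hip angle (deg) and
mass-normalized moment (Nm/kg) — from two limb-mounted IMUs and one
force-measuring insole, using a deliberately small feed-forward network.
Because trust in such a pipeline comes from validation against a gold
standard, the package carries three interlocking parts:

1. a **synthetic cohort generator** whose ground truth is known exactly,
2. a **planar inverse-dynamics surrogate** of the laboratory workflow, and
3. the **wearable network and its subject-wise cross-validation harness**.

## The synthetic generator

### Templates and their calibration

All curves over one gait cycle (0–100%, heel strike to heel strike) are
periodic cubic splines through hand-placed knots, calibrated on a dense
grid so that healthy-cohort landmarks are matched exactly:

| quantity | value | how it is enforced |
|---|---|---|
| sagittal hip angle at heel strike | 58.0 deg | affine calibration pins the 0% value |
| sagittal hip range of motion | 55.6 deg | affine calibration of the dense range |
| frontal hip range of motion | 17.4 deg | range scaling about the curve midpoint |
| peak flexion moment (near 50% gait) | 1.0 Nm/kg | global scale on the sagittal moment curve |
| first (larger) abduction peak | 1.6 Nm/kg | global scale on the frontal moment curve |
| stance fraction | 0.67 | GRF template support; insole events |

Angles follow the adduction/flexion-positive convention; moments are
reported flexion-positive (stance extensor action is negative) and
adduction-positive (the stance abductor moment is negative), matching the
sign pattern of the landmark table the templates are calibrated to.

Two geometric properties are built into the angle templates rather than
left to chance, because the event detectors key on them:

* **Optical heel strike.** The detector defines heel strike as the downward
  zero crossing of the heel marker's anteroposterior velocity after swing.
  The hip template therefore keeps flexing into heel strike (its true
  maximum, ≈59.4°, falls near 3% gait; the 0% value is exactly 58.0°), and
  a localized slope term makes the forward-kinematic heel velocity vanish
  exactly at 0%. Had the hip peaked exactly at 0%, the zero crossing would
  be degenerate and detection unstable under the 6 Hz marker filter.
* **IMU heel strike.** The shank angle is built by integrating a designed
  angular-velocity shape with the classic two-minima stance signature; the
  heel-strike dip is positioned so that, *after* the 2.3 Hz zero-phase
  filter the detector mandates, its minimum falls on the cycle boundary
  within about one sample across cycle durations 1.9–2.6 s (the raw dip is
  placed 0.85% of a cycle later to cancel the filter's context-induced
  displacement).

The knee and ankle shapes are stair-plausible fixtures supporting the
kinematic chain; they are not calibrated claims. The vertical GRF template
is a double bump (~1.2 body weight peaks over a ~0.9 body weight valley)
whose loading and unloading edges carry a brief linear toe through the
20 N detection band, so threshold crossings survive 10 Hz zero-phase
filtering essentially in place.

### Subject and trial variability

Per subject, the generator draws height ~ N(1.74, 0.08) m and mass ~
N(81.6, 19.5) kg (truncated positive), a mean cycle duration ~
N(2.21, 0.15) s (≈4.53 cycles per 10 s trial), a stance fraction ~
N(0.67, 0.034), one amplitude z-score and one offset z-score per plane
(amplitude scale SD 0.08; offsets SD 2° for angles, 0.05 Nm/kg for
moments), and per-cycle duration jitter (3%). Two design choices matter:

* The amplitude/offset z-scores are **shared between the angle and the
  moment of each plane**, and the shank curve shares the sagittal scale.
  Larger excursions therefore go with larger moments, and the per-subject
  moment variability is in principle recoverable from the motion the
  sensors record. Real cohorts also contain moment variability that
  kinematics cannot explain; the generator deliberately omits it, which is
  one reason synthetic performance exceeds real-data performance.
* The template cycle structure (toe off near 67%) is **fixed**, while the
  insole stance window follows each subject's drawn stance fraction.
  Retiming the curves to the drawn toe-off was tried and rejected: it
  displaces the shank-gyro heel-strike signature and biases the IMU
  detector by several samples at stance extremes.

Sensor noise defaults are small and consumer-grade: gyro 0.02 rad/s,
accelerometer 0.2 m/s², magnetometer 0.05 a.u., quaternion 0.002
(renormalized), insole 5 N, marker 0.3 mm. Trials begin just after a toe
off (gait phase 68%) so that the first heel strike is detectable on every
modality, and clock offsets up to ±0.4 s emulate unsynchronized hardware.
Ground-truth moments are template-defined rather than re-derived from the
synthetic GRF by inverse dynamics, so the calibration landmarks are exact;
dynamic consistency is validated separately in the dynamics module.

## The planar dynamics surrogate

The gold-standard surrogate works in a pelvis-fixed frame (x anterior, y
up, z lateral; hip joint centre at the origin, appropriate for a stair
exercise machine). Segment parameters come from Winter's anthropometric
table. Forward kinematics chains thigh, shank and foot in the sagittal
plane and tilts the chain about the anteroposterior axis by the frontal
hip angle. Virtual IMUs report segment angular velocity, proper
acceleration of the mid-segment mount point and a constant Earth-like
magnetic field, all expressed in a sensor frame offset about the segment's
longitudinal axis (121.3° for the anteromedial shank mount);
`rotate_shank_imu()` with the same angle is its exact inverse.

Hip inverse dynamics is bottom-up Newton–Euler over foot, shank and thigh
with the measured vertical force applied at the talus (the ankle joint
centre) — reproducing, rather than fixing, the gold standard's
centre-of-pressure simplification; an optional load-point offset exposes
its sensitivity (a 1 cm anterior shift increases the peak extension-phase
moment). The frontal plane is quasi-static: frontal inertial terms are
small during stair ascent and no frontal dynamic model is attempted.
Static correctness is pinned by an independent free-body oracle to
1e-6 Nm/kg in the test suite.

## The network and its training

The network is fixed at 28–5–5–4 with tanh hidden layers and a linear
output layer. Inputs and targets are min–max scaled to [−1, 1] (constant
columns, such as the per-trial activity duration, map to 0 and are
restored on inversion). Hidden layers are initialized by the
Nguyen–Widrow rule (row norms `0.7·H^(1/n_in)`, biases uniform in ±that);
the output layer starts uniform in ±0.5. Training is full-batch
Levenberg–Marquardt with an analytic Jacobian: λ starts at 1e-3, shrinks
×0.1 on accepted steps, grows ×10 on rejections, and training ends at
`max_epochs` (default 100), on damping overflow (recorded, with the best
weights retained), or when the gradient norm has not improved its running
minimum for more than 6 consecutive passes. The stall rule doubles as mild
early stopping; experiments with a laxer reading trained longer and
generalized worse. All randomness is seeded, and a fixed seed with fixed
data reproduces identical weights (single-threaded contract).

Training rows are thinned to every 8th sample (16 Hz effective) by
default: the curves are smooth and heavily oversampled at 128 Hz, held-out
prediction still runs at full rate, and the thinning keeps the 170-fit
cross-validation experiment in the minutes range on one CPU.

## Evaluation choices

* Per-iterate metrics are computed on the held-out subject's concatenated
  gait-normalized cycles (101 points each, from the insole events), not on
  raw samples, matching how such curves are compared in practice.
* `R²` defaults to `1 − SS_res/SS_tot` (it may be negative and is reported
  as computed); the squared-Pearson variant is available as
  `method = "cor"` because the literature uses both under one name.
* One initialization seed is drawn per training round and shared across
  held-out subjects, so aggregate results do not depend on subject order.
* Discrete-point paired t-tests run at 0/30/60/80% gait on subject-level
  mean curves; zero-variance differences are reported as degenerate
  (`t = 0, p = 1` only when the curves are bitwise identical) rather than
  as infinite statistics.
* Violin summaries drop values outside median ± 1.5·IQR, then fit a
  Gaussian KDE with Silverman's bandwidth.

## Numerical choices and degenerate inputs

* Zero-phase filtering anchors a line through the series endpoints,
  filters the residual with odd-reflection padding, and adds the line
  back: constants and ramps pass through exactly and edge transients stay
  below 1e-9 of signal scale.
* Resampling is linear interpolation onto a `floor((N−1)·r)+1`-point grid
  spanning the input interval;
  event threshold crossings take the earliest qualifying sample;
  quaternions are renormalized after any filtering or noise injection and
  compared up to the q ~ −q ambiguity.
* Streams reject quaternion norm errors beyond 1e-6, time-stamp jitter
  beyond 1% of a sample period, and dropouts longer than 0.1 s (shorter
  gaps are linearly interpolated).

## What the tests do and do not show

On zero-noise, zero-jitter cohorts the full pipeline closes: the network
memorizes the shared clean structure and held-out error collapses (each
output ≤ 5% rRMSE). With default subject jitter and zero sensor noise the
angles remain near-perfect, while held-out moments average ~4–5.5% rRMSE
(R² ≈ 0.97): occasional ±2σ-amplitude subjects are extrapolated
imperfectly by the ten-node network. With default sensor noise, the full
17-subject × 10-round experiment achieves overall mean rRMSE ≈ 3% and
R² ≈ 0.98 — comfortably better than the real-data bound it is checked
against (17.7% / 0.77), as expected for a generator that omits soft-tissue
artifact, magnetometer disturbance, marker occlusion, electromechanical
delays and the kinematics-independent part of inter-subject moment
variability. Passing these tests therefore demonstrates the correctness
and internal consistency of the workflow, not field performance on human
data.

Problem sizes used throughout the suite — 17 subjects, ~4.53 cycles per
trial, 101-point cycles, 10 rounds — mirror the cohort the generator
emulates; smaller cohorts appear in unit tests purely as minimal cases.

## Known limitations

* The surrogate is planar; transverse-plane mechanics and three-dimensional
  joint models are out of scope.
* Only the vertical GRF component is modeled, applied at a fixed talus
  point; centre-of-pressure travel is exposed only as a sensitivity offset.
* The insole's 20 N crossing detected after 10 Hz zero-phase filtering
  carries a residual early bias of roughly one 100 Hz sample on steep
  synthetic loading edges; synchronization is anchored to the optical heel
  strike, so the bias does not propagate to the feature/target alignment.
* Template toe-off structure is fixed at 67% of the cycle while subject
  stance fractions vary around it (see above).
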