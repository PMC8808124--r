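---
title: "Quaternion EKF sensor fusion and CNN activity recognition: methods"
author: "imuhar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quaternion EKF sensor fusion and CNN activity recognition: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imuhar)
```

This vignette is the package's own account of its methods: the sensor-fusion
model and its assumptions, the classifier and its training protocol, the
synthetic data the tests rest on, and the numerical and design choices made
where more than one reasonable option existed.

## The estimation problem

A body-worn inertial unit reports three 3-axis streams: angular rate from a
gyroscope (deg/s), specific force from an accelerometer (g), and the local
magnetic field from a magnetometer (Gauss). Orientation cannot be read off
any single sensor: integrating the gyro drifts without bound (its reading
includes a slowly varying additive bias), while the accelerometer and
magnetometer are noisy but anchored to two fixed reference directions —
gravity and magnetic north. The filter fuses the three.

The state is $x = (q, \omega_b)$: a unit quaternion $q = (q_0, q_1, q_2,
q_3)$ (scalar first, Hamilton products) giving the passive rotation from the
sensor frame $\{b\}$ to the navigation frame $\{n\}$, and the gyro bias
$\omega_b \in \mathbb{R}^3$ in rad/s, with a $7\times 7$ error covariance
$P$. Quaternions avoid the gimbal singularity that Euler angles suffer at
$\pm 90^\circ$ pitch; Euler angles appear only at the interface (initial
alignment and human-readable output), in the intrinsic z–x–y convention
$R_{b\to n} = R_z(\mathrm{yaw})\,R_x(\mathrm{pitch})\,R_y(\mathrm{roll})$.
That convention is forced by the initial-alignment formulas: under it, and
only under a convention of this family, `initial_euler()`'s tilt terms
$\mathrm{pitch} = \arcsin(a_y/\lVert a\rVert)$, $\mathrm{roll} =
\mathrm{atan2}(-a_x, a_z)$ and its tilt-compensated compass heading take
their textbook closed form.

### Prediction

Continuous-time quaternion kinematics $\dot q = \tfrac12\,\Omega(\omega)\,q$
are discretized over the sample interval $T$ by the first-order map

$$q^- = \left(I_4 + \tfrac{T}{2}\,\Omega(\hat\omega)\right) q,
\qquad \hat\omega = \omega_{\mathrm{meas}} - \omega_b,$$

with $\Omega$ the antisymmetric rate matrix (`omega_matrix()`) and the bias
propagated as identity. Two deliberate choices here:

* **Bias coupling.** The bias is subtracted from the gyro reading inside
  $\Omega$, and the transition Jacobian $G$ carries the corresponding
  $\partial q^-/\partial \omega_b = -\tfrac{T}{2}\,\Xi(q)$ block. Without
  this coupling the bias state would be decoupled from every measurement and
  therefore unobservable — it would sit inert at its initial value.
* **Normalization.** The linear update does not preserve the quaternion
  norm, so $q^-$ is renormalized after every prediction and every
  correction; the unit-norm invariant is enforced to $10^{-12}$ and checked
  in the tests.

Process noise is built from the two gyro noise intensities: the measurement
noise $\omega_n$ mapped onto quaternion coordinates through $\Xi(q)$ and
scaled by the step, and a bias random walk,

$$Q = \mathrm{blockdiag}\!\left(\left(\tfrac{T}{2}\right)^2 \omega_n\,
\Xi(q)\Xi(q)^{\mathsf T},\; T\,\omega_{bn} I_3\right).$$

This is the standard first-order discretization; the four noise scalars
(gyro, gyro bias, accel, mag) are exposed in `noise_config()` because the
source protocol treats them as free parameters.

### Correction

The measurement vector stacks the normalized accelerometer and magnetometer
readings. Its prediction from the prior orientation:

* gravity: $\bar a^b = R_{b\to n}^{\mathsf T}\, (0,0,1)^{\mathsf T}$;
* magnetic field: the measured field is rotated into $\{n\}$, its east
  component is collapsed by folding the horizontal magnitude into north —
  the model assumes the local field has only north and vertical components —
  and the result is rotated back into $\{b\}$.

The east-collapse makes the magnetometer constrain only the heading, so hard
tilt errors cannot leak in through magnetic disturbance. Its sign convention
(horizontal magnitude goes to $+$north) is one of two defensible readings of
the underlying model; it is fixed here and documented. The measurement
Jacobian $H$ is computed analytically, including the full dependence of the
east-collapse on $q$ (both rotations and the fold), and is verified against
central finite differences at relative tolerance $10^{-6}$ in the
acceptance suite; the transition Jacobian likewise.

Gain, covariance and state follow the standard EKF equations
$K = P^- H^{\mathsf T}(H P^- H^{\mathsf T} + R)^{-1}$,
$P = (I - KH)P^-$ (symmetrized), $x = x^- + K(Z - h(q^-))$, with
$R = \mathrm{blockdiag}(a_n I_3, m_n I_3)$.

Degenerate inputs: a near-zero accelerometer reading (free fall) skips the
accelerometer half of the correction with a warning, a near-zero
magnetometer reading skips the magnetic half, and a singular innovation
covariance aborts with a diagnostic rather than silently regularizing.

### Filter defaults

The protocol source gives no numeric covariances, so the defaults are set to
sensor-realistic orders of magnitude: gyro noise $3\times10^{-5}$
(rad/s)² (≈ 0.3 deg/s rms, consumer MEMS), bias walk $10^{-8}$, accel/mag
$10^{-3}$ in normalized units, initial $P$ of $10^{-4}$ on the quaternion
block (the first-sample alignment is already good) and $3\times10^{-4}$ on
the bias block (≈ 1 deg/s prior uncertainty). They are defaults, not
constants: every one is a `noise_config()` argument.

## Synthetic data: what it emulates and what it does not

`simulate_imu()` draws a smooth orientation trajectory (per-angle sinusoids,
constants allowed), computes the exact body angular rate analytically from
the Euler rates, and synthesizes sensors from the ground truth: gyro = true
rate + constant bias + white noise (deg/s), accel = rotated gravity + noise,
mag = rotated reference field + noise. The magnetic reference has north and
vertical components only, matching the measurement model. Defaults are the
study conditions used throughout the tests: 60 s at 100 Hz, bias $(0.5, 0,
0)$ deg/s, noise 0.3 deg/s / 0.01 g / 0.005 Gauss. The generator is a pure
function of its spec (seed included).

What it does not emulate: linear acceleration of the wearer (the
accelerometer sees gravity only), magnetic disturbance, sensor scale-factor
or axis-misalignment errors, temperature-dependent bias drift, and
timestamp jitter. Passing tests therefore demonstrate correctness of the
*filter*, under its own model assumptions — not robustness to the ways real
wearables violate them.

`simulate_activity_streams()` builds the classification fixture: each
activity class has a distinct dominant frequency ($3.3 + 2.4(c-1)$ Hz) and a
per-channel amplitude signature (one rotating dominant channel at amplitude
2.0, others at 0.5), plus additive noise (sd 0.1 — a high-SNR regime). Two
generator choices matter:

* The frequencies are deliberately incommensurate with the 32-sample /
  32 Hz window, so the oscillation phase drifts across a user's consecutive
  windows — as it would in any continuously recorded stream. Phase diversity
  within the training users is what lets a classifier generalize to the
  held-out user's unseen phases.
* Per-user random phases make leave-one-subject-out validation meaningful:
  the held-out user is genuinely unseen.

These streams are *class-conditioned signals placed in sensor columns*, not
physically consistent IMU readings; running the fusion filter on them is
well-defined but its orientation output carries no class information. The
cross-validated evaluation of the fixture therefore uses raw channels,
while `features: raw+fused` remains the pipeline default for real sensor
data, where orientation is exactly the summary a classifier should see.

## Windowing and the evaluation protocol

Streams are cut into fixed windows (`slice_windows()`), without overlap
(stride = length) or with half overlap (stride = length/2), trailing
partial windows dropped; both modes are first-class because the protocol
names both without committing. A window spanning a label transition takes
the majority label, ties to the earliest-occurring label — the source is
silent, so the rule is fixed and stated; optionally windows with more than a
configurable minority fraction can be dropped (off by default).

Evaluation is leave-one-subject-out: one fold per user, that user's windows
held out entirely. Per fold, one-vs-rest counts per class feed the indices

$$A = \frac{TP + TN}{TP + TN + FP + FN}, \qquad
R = \frac{TP}{TP + FP}, \qquad
F_1 = \frac{2AR}{A + R},$$

macro-averaged over classes. $R$'s denominator is implemented exactly as the
protocol prints it — which is the denominator usually associated with
precision; the conventional $TP/(TP+FN)$ is available behind
`convention = "tp_fn"` and the output labels which was used. Across folds
each metric is aggregated by a trimmed mean that discards the single best
and single worst fold (a guard against one unusually clean or noisy
subject); with fewer than four folds a plain mean is used with a warning.

## The classifier and its training protocol

The reference model is one convolution layer (8 kernels, default kernel
$3\times3$ with height capped at the input height, so $1\times3$ over
time-series windows), ReLU, two-stage max pooling with $n = 2$ (block
height likewise capped), a dense layer and softmax. Windows enter as
channels × 1 × time; all of it is configurable.

Two operators implement the published dataflow and are held to semantic
equivalence with their naive forms by oracle tests:

* `conv2d_tiled()` splits input channels into tiles of width $N$,
  accumulates each tile's partial sums over all kernel positions and all
  kernels, then accumulates tiles along the channel direction. A channel
  count not divisible by $N$ leaves a shorter tail tile. The schedule is a
  dataflow description — the result equals dense convolution to $10^{-9}$
  over a shape sweep.
* `maxpool_two_stage()` factors $n\times n$/stride-$n$ max pooling into a
  horizontal then a vertical pass; incomplete edge blocks are dropped.
  Equal to the naive block maximum, exactly.

Unstated details are filled and flagged: valid (zero) padding and stride 1
by default, ReLU between convolution and pooling, symmetric uniform
fan-in-scaled weight initialization, seeded.

Training follows the published protocol: Adadelta, learning rate 0.001,
softmax cross-entropy, stop when the training loss reaches 0.2 or after
200 iterations. The remaining optimizer constants are the package's own
choices, and two of them deserve their rationale spelled out, because with
the learning rate fixed at 0.001 they decide whether the stop rule is
reachable *at all*:

* **Batch size 4 (one iteration = one pass over the training set, fixed
  batch order, so training is deterministic).** Adadelta rescales each step
  by the ratio of running update and gradient magnitudes; a global
  multiplier of 0.001 makes individual steps small, so the iteration budget
  is only sufficient if each iteration applies many updates. Full-batch
  descent would perform exactly 200 updates and cannot leave the
  optimizer's warm-up regime before the cap — with this protocol it stalls
  near the initial loss on any problem. Minibatch is also how this
  optimizer family is used in practice.
* **Stabilizer $\epsilon = 10^{-2}$.** The first Adadelta step is
  $\approx \mathrm{lr}\cdot\sqrt{\epsilon}$ per unit normalized gradient,
  so $\epsilon$ sets the warm-up step scale. The customary $10^{-6}$ is
  tuned to $\mathrm{lr} = 1$; under $\mathrm{lr} = 0.001$ it keeps steps
  three orders of magnitude smaller and the 200-iteration budget is spent
  entirely in warm-up. $10^{-2}$ restores a usable warm-up scale for
  inputs of order one.

Both are `train_config()` arguments; nothing in the package depends on them
beyond the defaults. Gradients are analytic (softmax/cross-entropy through
dense, pooling argmax routing, ReLU mask, convolution via the shared
im2col), and the acceptance suite checks every coordinate of a small model
against central finite differences at relative $10^{-5}$.

On the default fixture (5 users × 3 classes × 8 windows, high SNR) each
leave-one-subject-out fold trains on 96 windows; folds typically reach the
loss threshold between iterations 100 and 200, and held-out users are
classified essentially perfectly. These problem sizes were chosen so the
whole cross-validation completes in well under a minute on one core while
still exercising every protocol element (multiple users, classes, folds,
early stopping, trimmed aggregation).

## Numerical choices and degenerate inputs, collected

* Quaternion sign: $q$ and $-q$ encode one rotation; comparisons use
  $|\langle q_1, q_2\rangle|$.
* $P$ is symmetrized as $(P + P^{\mathsf T})/2$ after every step; tests
  assert eigenvalues $\ge -10^{-10}$.
* Euler output clamps $\arcsin$ arguments to $[-1, 1]$ against rounding at
  gimbal lock.
* Pitch at exactly $\pm\pi/2$ makes roll/yaw individually undefined
  (only their combination is); conversions are tested away from that set.
* Zero accelerometer or magnetometer vectors at initial alignment are
  errors (no orientation is defined); during filtering they skip the
  affected measurement half with a warning instead, since the stream
  continues.
* Streams shorter than one window yield an empty window list with a
  warning, not an error.
* Pooling argmax ties route gradients to the first maximum.

## Known limitations

* The filter assumes a static-dominated accelerometer; sustained linear
  acceleration biases the tilt estimate. Real deployments interpose a
  detector or adaptive $R$; out of scope here.
* The magnetometer model assumes a disturbance-free field; indoor
  environments violate this routinely.
* The classifier is the reference architecture of the published dataflow,
  not a competitive modern HAR network; its purpose is faithful operator
  semantics and protocol reproduction at desk scale.
* Public benchmark datasets (and numbers reported on them) are outside the
  package's scope; all empirical statements here are about the synthetic
  generators, computed by the test suite and the acceptance script.
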