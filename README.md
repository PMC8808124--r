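# imuhar

Sensor fusion and activity recognition for wearable inertial devices, in R.

Body-worn IMUs report three noisy, complementary streams: gyroscope angular
rate (deg/s), accelerometer specific force (g) and magnetometer field
(Gauss). `imuhar` implements the two-stage pipeline used to turn such
streams into recognized activities:

1. **Orientation fusion.** An extended Kalman filter with state
   $x = (q, \omega_b)$ — a unit quaternion (sensor frame → navigation
   frame, Hamilton convention, scalar first) plus the gyro bias — and a
   7×7 covariance. The gyro drives the discretized quaternion kinematics
   $q^- = (I + \tfrac{T}{2}\Omega(\omega - \omega_b))\,q$; accelerometer
   and magnetometer corrections anchor the estimate to the gravity
   reference $g = (0,0,1)^{\mathsf T}$ and a magnetic field with north and
   vertical components only (the east component of the measured field is
   collapsed before use, so magnetics constrain heading only). Analytic
   Jacobians throughout, verified against finite differences in the tests.
2. **Recognition.** Labeled streams are cut into fixed windows
   (non-overlapping or half-overlapping), classified by a small CNN built
   from two explicitly scheduled operators — channel-tiled multi-filter
   convolution (`conv2d_tiled()`) and two-stage max pooling
   (`maxpool_two_stage()`), each oracle-tested against its naive
   equivalent — and trained with Adadelta (lr 0.001) under an
   early-stopping rule (loss ≤ 0.2 or 200 iterations). Evaluation is
   leave-one-subject-out with per-class one-vs-rest indices
   $A = (TP{+}TN)/(TP{+}TN{+}FP{+}FN)$, $R = TP/(TP{+}FP)$ (as printed in
   the protocol this package follows; the conventional $TP/(TP{+}FN)$ is a
   flag away), $F_1 = 2AR/(A{+}R)$, macro-averaged, aggregated across
   folds by a trimmed mean that drops the single best and worst fold.

A synthetic-data module generates IMU streams with exact ground-truth
orientation (and injected gyro bias), and labeled multi-user activity
streams with class-specific spectral/amplitude signatures, so every claim
above is testable without external datasets. See the methods vignette
(`vignettes/sensor-fusion-har.Rmd`) for the model, assumptions, defaults
and design decisions.

## Worked example

Fuse a simulated stream with an injected 0.5 deg/s x-axis gyro bias, and
compare against gyro-only dead reckoning:

```r
library(imuhar)

sim <- simulate_imu(trajectory_spec(duration = 60, rate = 100, seed = 42))
sim$sequence
#> <imu_sequence> user user1: 6000 samples at 100 Hz (60.00 s)

fit <- run_filter(sim$sequence)
fit
#> <ekf_fit> 6000 samples at 100 Hz; final bias estimate (deg/s): 0.5024, -0.0076, -0.0008

dr <- dead_reckoning(sim$sequence)
rms_deg <- function(e) 180 / pi * sqrt(mean(
  (e$pitch - sim$truth$pitch)^2 + (e$roll - sim$truth$roll)^2 +
  (e$yaw - sim$truth$yaw)^2))
c(ekf = rms_deg(fit$estimates), gyro_only = rms_deg(dr))
#>    ekf   gyro_only
#>  0.109      15.835
```

The filter recovers the injected bias to half a percent and holds the
orientation error two orders of magnitude below dead reckoning, whose
error is dominated by the uncorrected bias drift.

Cross-validated activity recognition on the synthetic 5-user, 3-class
fixture (raw sensor channels):

```r
res <- cmd_xval(pipeline_config(list(features = "raw")),
                metrics_path = NULL, seed = 42)
#> LOSO 5 folds; trimmed means A=1.0000 R=1.0000 F1=1.0000 accuracy=1.0000
res$per_fold[c("user", "A", "R", "F1", "accuracy", "stop_reason")]
#>    user A R F1 accuracy stop_reason
#> 1 user1 1 1  1        1   loss_stop
#> 2 user2 1 1  1        1   loss_stop
#> 3 user3 1 1  1        1   loss_stop
#> 4 user4 1 1  1        1   loss_stop
#> 5 user5 1 1  1        1   loss_stop
```

Every fold halts on the loss ≤ 0.2 rule and the held-out users are
classified perfectly: the class signatures are separable at this SNR, and
the `stop_reason` column records which half of the stopping rule fired.

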