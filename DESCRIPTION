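Package: imuhar
Title: IMU Sensor Fusion and Activity Recognition for Wearable Devices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Feature extraction and human-activity recognition for wearable
    inertial sensors. Fuses gyroscope, accelerometer and magnetometer streams
    into a quaternion orientation estimate with online gyro-bias estimation
    using an extended Kalman filter, segments labeled streams into fixed-length
    windows, classifies them with a small convolutional network built from
    explicit channel-tiled convolution and two-stage max-pooling operators
    trained with Adadelta, and evaluates with leave-one-subject-out
    cross-validation using accuracy, recall and F1. Includes a synthetic IMU
    and activity-stream generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
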