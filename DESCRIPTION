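Package: imuposture
Title: Posture Monitoring and Joint-Angle Measurement from IMU Orientation Streams
Version: 1.0.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for wearable-sensor posture monitoring built on unit-quaternion
    kinematics. Implements exact quaternion algebra with an explicit Euler
    convention and gimbal-lock policy, three joint-angle measurement methods
    over parent/child segment orientation pairs, reference-pose (re-zeroing)
    calibration, a 13-segment body model with scenario-specific range-of-motion
    limits and sustained-violation detection, a newline-delimited JSON packet
    dialect with CSV logging, a seeded synthetic-motion simulator that stands in
    for physical 9-axis IMUs, and a goniometer-sweep validation harness with
    accuracy summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
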