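Package: gait6dof
Title: Six-Degrees-of-Freedom and Conventional Gait Model Lower-Limb Kinematics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Clinical gait kinematics from optical motion capture with two
    lower-limb protocols: a six-degrees-of-freedom marker-cluster model using
    the calibrated anatomical systems technique (pointer-based landmark
    calibration, virtual-marker reconstruction, ISB anatomical frames) and the
    conventional Helen Hayes/Davis wand-marker model.  Includes SVD rigid-body
    pose estimation, pivot calibration of a tracked pointer, the Davis hip
    joint centre regression, Cardan joint-angle decomposition, zero-lag
    Butterworth trajectory filtering, gait-cycle detection and 101-point time
    normalisation, repeatability statistics (intertrial and intraprotocol
    variability, mean absolute variability, range of motion), a documented CSV
    dialect and a minimal C3D reader/writer, and a forward-kinematic synthetic
    gait generator with controllable noise, soft-tissue artefact and axis
    misalignment for validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
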