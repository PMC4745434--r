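test_that("angle-curve generation is deterministic and well-dispersed", {
  cfg <- simulation_config(seed = 77)
  a <- generate_angle_curves(cfg, 2, 3)
  b <- generate_angle_curves(cfg, 2, 3)
  expect_identical(a, b)                           # same seed, same curves
  cfg0 <- simulation_config(sigma_trial = 0, tau_subject = 0, seed = 77)
  for (j in 1:2) for (i in 1:2)
    expect_equal(unname(generate_angle_curves(cfg0, j, i)),
                 unname(gait_template_curves(seq(0, 1, length.out = 101))),
                 ignore_attr = TRUE)
  # marginal variance of the injected trial effects ~ sigma^2
  offs <- replicate(400, {
    cfgk <- simulation_config(n_subjects = 1, tau_subject = 0,
                              seed = sample.int(1e6, 1))
    attr(generate_angle_curves(cfgk, 1, sample(3, 1)), "offsets")[1]
  })
  expect_equal(var(offs), 1.0, tolerance = 0.25)
  # realised within-subject SD is exactly sigma for every rotation
  cfg1 <- simulation_config(seed = 123)
  off3 <- sapply(1:3, function(i)
    attr(generate_angle_curves(cfg1, 1, i), "offsets"))
  expect_equal(unname(apply(off3, 1, sd)), rep(1, 12), tolerance = 1e-9)
})

test_that("forward kinematics inverts to zero ankle angles at neutral", {
  subj <- synthetic_subject()
  fk <- forward_kinematics(subj, matrix(0, 4, 12), rep(0, 4), 100,
                           stride_length_mm = 0)
  ja <- compute_joint_angles(fk$segment_poses)
  expect_lt(max(abs(ja$angles)), 1e-10)
  # gimbal-range refusal
  bad <- matrix(0, 2, 12); bad[, 5] <- 95
  expect_error(forward_kinematics(subj, bad, c(0, 0), 100), "gimbal")
})

test_that("prescribed angles survive the forward/inverse round trip", {
  subj <- synthetic_subject()
  tt <- seq(0, 1, length.out = 51)
  ang <- gait_template_curves(tt)
  fk <- forward_kinematics(subj, ang, tt, 100)
  ja <- compute_joint_angles(fk$segment_poses)
  expect_lt(max(abs(ja$angles - ang)), 1e-9)
})

test_that("joint angles are invariant under a rigid lab transform", {
  set.seed(83)
  subj <- synthetic_subject()
  tt <- seq(0, 1, length.out = 21)
  ang <- gait_template_curves(tt)
  base <- compute_joint_angles(
    forward_kinematics(subj, ang, tt, 100)$segment_poses)
  mv <- random_pose()
  moved <- compute_joint_angles(
    forward_kinematics(subj, ang, tt, 100, lab_frame = mv)$segment_poses,
    lab_frame = mv)
  expect_lt(max(abs(moved$angles - base$angles)), 1e-9)
})

test_that("artefact injection is controllable and localised", {
  subj <- synthetic_subject()
  tt <- seq(-0.2, 1.2, by = 0.01)
  ang <- gait_template_curves(tt)
  fk <- forward_kinematics(subj, ang, tt, 100)
  seg_map <- synthetic_segment_map(subj)
  cfg0 <- simulation_config(marker_noise_sd = 0, sigma_trial = 0,
                            tau_subject = 0, seed = 9)
  same <- apply_artifacts(fk$markers, cfg0, tt, seg_map)
  expect_equal(same$pos, fk$markers$pos)           # zero amplitudes: no-op

  # noise-only at 0.5 mm on ~100 mm clusters: angle RMSE stays below 1 deg
  set.seed(19)
  cfgn <- simulation_config(marker_noise_sd = 0.5, sigma_trial = 0,
                            tau_subject = 0, seed = 19)
  noisy <- apply_artifacts(fk$markers, cfgn, tt, seg_map)
  study <- noise_free_study()
  sj <- study$subjects[[1]]
  cfg_isb <- synthetic_config(subj, "isb6dof")
  calib <- calibrate_subject(sj$calibration$static, sj$calibration$pivot,
                             sj$calibration$registration, cfg_isb)
  ta <- trial_angles_isb(noisy, calib, cfg_isb,
                         events = c(21, 121), cutoff = NULL)
  truth <- gait_template_curves(seq(0, 1, length.out = 101))
  rmse <- sqrt(mean((ta$cycles[[1]] - truth)^2))
  expect_gt(rmse, 0)
  expect_lt(rmse, 1)

  # STA on the thigh cluster only: knee and hip biased, pelvis/ankle not
  cfgs <- simulation_config(marker_noise_sd = 0, sigma_trial = 0,
                            tau_subject = 0,
                            sta_amplitude = list(femur = 10), seed = 9)
  sta <- apply_artifacts(fk$markers, cfgs, tt, seg_map)
  tas <- trial_angles_isb(sta, calib, cfg_isb, events = c(21, 121),
                          cutoff = NULL)
  dev <- apply(abs(tas$cycles[[1]] - truth), 2, max)
  expect_gt(dev[["knee_flex_ext"]], 0.5)
  expect_gt(dev[["hip_flex_ext"]], 0.5)
  expect_lt(dev[["pelvis_tilt"]], 1e-6)
  expect_lt(dev[["ankle_dor_pla"]], 1e-6)
})

test_that("study generation is reproducible and self-consistent on disk", {
  cfg <- simulation_config(n_subjects = 2, n_trials = 2,
                           marker_noise_sd = 0.3, seed = 2024)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_study(cfg, d1, format = "csv")
  generate_study(cfg, d2, format = "csv")
  m1 <- readLines(file.path(d1, "manifest.yaml"))
  m2 <- readLines(file.path(d2, "manifest.yaml"))
  expect_identical(m1, m2)                         # same seed, same study
  back <- read_study(d1)
  expect_length(back$subjects, 2L)
  tr <- back$subjects[[2]]$trials[[1]]
  regen <- generate_angle_curves(cfg, 2, 1)
  expect_lt(max(abs(tr$truth_angles - regen)), 1e-8)
  expect_equal(tr$events, c(21L, 121L))
})
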