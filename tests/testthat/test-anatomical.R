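test_that("Davis regression places the hip joint centre as published", {
  # hand evaluation of the published equations for L = 900, d_ASIS = 240,
  # d_AT from its own regression, marker radius 10
  L <- 900; dA <- 240; r <- 10
  C <- 0.115 * L - 15.3
  dAT <- 0.1288 * L - 48.56
  th <- 28.4 * pi / 180; be <- 18 * pi / 180
  hjc <- davis_hip_joint_centre(L, dA, marker_radius = r, side = "right")
  expect_equal(hjc$position[1], C * cos(th) * sin(be) - (dAT + r) * cos(be))
  expect_equal(hjc$position[2], -C * cos(th) * cos(be) - (dAT + r) * sin(be))
  expect_equal(hjc$position[3], dA / 2 - C * sin(th))
  expect_gt(hjc$position[3], 0)          # right side lateral
  expect_lt(hjc$position[2], 0)          # inferior to the ASIS plane

  # left/right mirror symmetry across the sagittal plane
  l <- davis_hip_joint_centre(L, dA, marker_radius = r, side = "left")
  expect_equal(l$position * c(1, 1, -1), hjc$position)

  # leg-length-dependent terms scale with C and dAT only
  h2 <- davis_hip_joint_centre(2 * L, dA, marker_radius = r)
  C2 <- 0.115 * 2 * L - 15.3; dAT2 <- 0.1288 * 2 * L - 48.56
  expect_equal(h2$position[1],
               C2 * cos(th) * sin(be) - (dAT2 + r) * cos(be))
  # marker radius enters only through the documented offset term
  h0 <- davis_hip_joint_centre(L, dA, marker_radius = 0)
  expect_equal(hjc$position - h0$position,
               c(-r * cos(be), -r * sin(be), 0))
  expect_error(davis_hip_joint_centre(-1, dA), "leg_length")
  expect_error(davis_hip_joint_centre(L, 0), "inter_asis")
})

test_that("ISB frames are recovered exactly from a constructed skeleton", {
  subj <- synthetic_subject()
  nf <- 3
  neutral <- matrix(0, nf, 12)
  fk <- forward_kinematics(subj, neutral, rep(0, nf), 100,
                           stride_length_mm = 0)
  hjc <- davis_hip_joint_centre(subj$anthropometrics$leg_length,
                                subj$anthropometrics$inter_asis)
  frames <- build_isb_frames(fk$landmarks, hjc)
  for (seg in c("pelvis", "femur", "shank")) {
    for (f in 1:nf) {
      expect_lt(max(abs(frames[[seg]]$R[, , f] -
                          fk$segment_poses[[seg]]$R[, , f])), 1e-9)
      expect_true(is_valid_rotation(frames[[seg]]$R[, , f]))
    }
  }
  # neutral: foot anatomical frame == shank anatomical frame
  off <- foot_neutral_offset(
    pose(frames$shank$R[, , 1], frames$shank$t[, 1], check = FALSE),
    pose_at(fk$segment_poses$foot, 1))
  rel <- relative_rotation(pose_at(fk$segment_poses$foot, 1),
                           pose(frames$shank$R[, , 1],
                                frames$shank$t[, 1], check = FALSE))
  expect_lt(max(abs(off$R - rel)), 1e-12)
})

test_that("frame construction is equivariant under rigid motion", {
  set.seed(31)
  subj <- synthetic_subject()
  ang <- gait_template_curves(c(0.2, 0.55))
  fk <- forward_kinematics(subj, ang, c(0.2, 0.55), 100)
  hjc <- davis_hip_joint_centre(subj$anthropometrics$leg_length,
                                subj$anthropometrics$inter_asis)
  base <- build_isb_frames(fk$landmarks, hjc)
  for (q in 1:5) {
    mv <- random_pose()
    moved <- marker_trajectory_set(lapply(fk$landmarks$pos, function(m)
      pose_apply(mv, m)), 100)
    got <- build_isb_frames(moved, hjc)
    for (seg in c("pelvis", "femur", "shank")) for (f in 1:2)
      expect_lt(max(abs(got[[seg]]$R[, , f] -
                          mv$R %*% base[[seg]]$R[, , f])), 1e-9)
  }
})

test_that("missing or degenerate landmarks raise named errors", {
  subj <- synthetic_subject()
  fk <- forward_kinematics(subj, matrix(0, 2, 12), c(0, 0), 100)
  hjc <- davis_hip_joint_centre(860, 240)
  crippled <- marker_trajectory_set(
    fk$landmarks$pos[setdiff(names(fk$landmarks$pos), "RLEPI")], 100)
  expect_error(build_isb_frames(crippled, hjc), "femur.*RLEPI")
  degen <- fk$landmarks$pos
  degen$LASIS <- degen$RASIS
  expect_error(build_isb_frames(marker_trajectory_set(degen, 100), hjc),
               "degenerate")
})

test_that("chord construction solves the perpendicularity condition", {
  set.seed(33)
  for (q in 1:25) {
    prox <- rnorm(3, 0, 100)
    lateral <- prox + c(rnorm(2, 0, 50), -400)
    wand <- prox + rnorm(3, 0, 150)
    d <- runif(1, 20, 60)
    jc <- chord_joint_centre(prox, lateral, wand, d)
    expect_equal(sqrt(sum((jc - lateral)^2)), d, tolerance = 1e-9)
    expect_lt(abs(sum((jc - lateral) * (jc - prox))), 1e-6)
    # coplanarity with the wand plane
    n <- c(crossprod(rbind((wand - lateral)), rbind(prox - lateral)))
    nrm <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                            a[3] * b[1] - a[1] * b[3],
                            a[1] * b[2] - a[2] * b[1])
    nv <- nrm(wand - lateral, prox - lateral)
    expect_lt(abs(sum((jc - lateral) * nv)) / sqrt(sum(nv^2)), 1e-6)
  }
  expect_error(chord_joint_centre(c(0, 0, 0), c(0, -30, 0), c(50, 0, 0),
                                  45), "offset")
})

test_that("conventional frames match ISB frames when wands are true", {
  # wand exactly in the femoral frontal plane: both protocols build the
  # same femur frame from one ground-truth skeleton
  subj <- synthetic_subject(wand_misalignment_deg = 0)
  tt <- c(0, 0.3, 0.7)
  ang <- gait_template_curves(tt)
  fk <- forward_kinematics(subj, ang, tt, 100)
  hjc <- davis_hip_joint_centre(subj$anthropometrics$leg_length,
                                subj$anthropometrics$inter_asis)
  isb <- build_isb_frames(fk$landmarks, hjc)
  hh <- build_hh_frames(fk$markers, hjc, synthetic_config(subj, "hh"))
  for (f in seq_along(tt)) {
    dR <- t(isb$femur$R[, , f]) %*% hh$femur$R[, , f]
    ang_err <- acos(min(1, (sum(diag(dR)) - 1) / 2)) * 180 / pi
    expect_lt(ang_err, 1e-6)
  }
  # a 10 deg axial wand misalignment rotates the thigh frame axially
  subj10 <- synthetic_subject(wand_misalignment_deg = 10)
  fk10 <- forward_kinematics(subj10, ang, tt, 100)
  hh10 <- build_hh_frames(fk10$markers, hjc, synthetic_config(subj10, "hh"))
  dR <- t(isb$femur$R[, , 1]) %*% hh10$femur$R[, , 1]
  a <- cardan_decompose(dR, "yzx")   # leading axial component
  expect_gt(abs(a[1]), 5)
  expect_lt(abs(a[1]), 15)
})

test_that("missing conventional markers are reported by role", {
  subj <- synthetic_subject()
  fk <- forward_kinematics(subj, matrix(0, 2, 12), c(0, 0), 100)
  hjc <- davis_hip_joint_centre(860, 240)
  cfg <- synthetic_config(subj, "hh")
  m <- fk$markers$pos
  m[["HH_RTHI"]] <- NULL
  expect_error(build_hh_frames(marker_trajectory_set(m, 100), hjc, cfg),
               "thigh wand")
})
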