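test_that("Cardan decomposition inverts composition", {
  expect_equal(as.numeric(cardan_decompose(diag(3))), c(0, 0, 0))
  expect_equal(as.numeric(cardan_decompose(rot_z(30 * pi / 180))),
               c(30, 0, 0), tolerance = 1e-12)
  set.seed(21)
  for (sq in c("zxy", "xyz", "zyx", "yxz")) {
    Rs <- random_rotations(125)
    for (q in 1:125) {
      a <- cardan_decompose(Rs[, , q], sq)
      expect_lt(max(abs(cardan_compose(as.numeric(a), sq) - Rs[, , q])),
                1e-10)
      expect_lt(abs(a[2]), 90)
    }
  }
})

test_that("gimbal proximity is flagged and handled", {
  a <- cardan_decompose(cardan_compose(c(10, 89.95, 5)))
  expect_true(attr(a, "gimbal"))
  b <- cardan_decompose(cardan_compose(c(10, 45, 5)))
  expect_false(attr(b, "gimbal"))
  # exact lock: recomposition still reproduces the matrix
  Rl <- cardan_compose(c(25, 90, 0))
  al <- cardan_decompose(Rl)
  expect_lt(max(abs(cardan_compose(as.numeric(al)) - Rl)), 1e-9)
})

test_that("relative rotation composes along kinematic chains", {
  set.seed(23)
  A <- random_pose(); B <- random_pose(); C <- random_pose()
  expect_equal(relative_rotation(A, A), diag(3), tolerance = 1e-12)
  expect_equal(relative_rotation(pose(), B), B$R, tolerance = 1e-12)
  expect_equal(relative_rotation(A, B) %*% relative_rotation(B, C),
               relative_rotation(A, C), tolerance = 1e-12)
})

test_that("neutral frames give identically zero angles", {
  nf <- 5
  id <- as_pose_series(replicate(nf, pose(), simplify = FALSE))
  frames <- list(pelvis = id, femur = id, shank = id, foot = id)
  ja <- compute_joint_angles(frames)
  expect_true(all(abs(ja$angles) < 1e-12))
  expect_identical(colnames(ja$angles), rotation_labels())
})

test_that("pure anatomical rotations carry the clinical signs", {
  mk <- function(pel = diag(3), fem = diag(3), shk = diag(3),
                 fot = diag(3)) {
    one <- function(R) as_pose_series(list(pose(R, c(0, 0, 0),
                                                check = FALSE)))
    list(pelvis = one(pel), femur = one(fem), shank = one(shk),
         foot = one(fot))
  }
  th <- 20 * pi / 180
  # hip flexion: femur -Y axis swings anterior = rotation about +Z
  ja <- compute_joint_angles(mk(fem = rot_z(th), shk = rot_z(th),
                                fot = rot_z(th)))
  expect_equal(ja$angles[1, "hip_flex_ext"], 20, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_lt(max(abs(ja$angles[1, c("hip_abd_add", "hip_int_ext",
                                   "knee_flex_ext")])), 1e-9)
  # knee flexion: shank rotates about -Z relative to femur
  ja <- compute_joint_angles(mk(shk = rot_z(-th), fot = rot_z(-th)))
  expect_equal(ja$angles[1, "knee_flex_ext"], 20, tolerance = 1e-9,
               ignore_attr = TRUE)
  # hip adduction (right limb): about +X
  ja <- compute_joint_angles(mk(fem = rot_x(th), shk = rot_x(th),
                                fot = rot_x(th)))
  expect_equal(ja$angles[1, "hip_abd_add"], 20, tolerance = 1e-9,
               ignore_attr = TRUE)
  # hip internal rotation (right limb): about +Y
  ja <- compute_joint_angles(mk(fem = rot_y(th), shk = rot_y(th),
                                fot = rot_y(th)))
  expect_equal(ja$angles[1, "hip_int_ext"], 20, tolerance = 1e-9,
               ignore_attr = TRUE)
  # ankle dorsiflexion: foot about +Z
  ja <- compute_joint_angles(mk(fot = rot_z(th)))
  expect_equal(ja$angles[1, "ankle_dor_pla"], 20, tolerance = 1e-9,
               ignore_attr = TRUE)
  # pelvis anterior tilt: anterior axis dips, rotation about -Z
  ja <- compute_joint_angles(mk(pel = rot_z(-th), fem = rot_z(-th),
                                shk = rot_z(-th), fot = rot_z(-th)))
  expect_equal(ja$angles[1, "pelvis_tilt"], 20, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("a fixed axial misalignment turns flexion into cross-talk", {
  # conjugating a pure flexion by a rotation about the longitudinal axis
  # induces spurious middle/third angles that grow with flexion, matching
  # the closed-form decomposition of the composed matrix
  phi <- 15 * pi / 180
  for (th_deg in c(10, 30, 60)) {
    th <- th_deg * pi / 180
    R <- t(rot_y(phi)) %*% rot_z(th) %*% rot_y(phi)
    a <- cardan_decompose(R)
    expect_equal(a[2], asin(-sin(phi) * sin(th)) * 180 / pi,
                 tolerance = 1e-9, ignore_attr = TRUE)
    g_expect <- atan2(sin(phi) * cos(phi) * (1 - cos(th)),
                      sin(phi)^2 * cos(th) + cos(phi)^2) * 180 / pi
    expect_equal(a[3], g_expect, tolerance = 1e-9, ignore_attr = TRUE)
  }
  # spurious rotation grows monotonically with flexion
  g <- sapply(c(10, 30, 60), function(d) {
    abs(cardan_decompose(t(rot_y(phi)) %*% rot_z(d * pi / 180) %*%
                           rot_y(phi))[3])
  })
  expect_true(all(diff(g) > 0))
})

test_that("unwrapping removes +/-180 degree jumps", {
  x <- c(170, 178, -179, -172, -168)
  y <- unwrap_degrees(x)
  expect_true(all(abs(diff(y)) < 20))
  expect_equal(y[1], 170)
})
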