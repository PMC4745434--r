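test_that("rigid transform fit recovers constructed transforms exactly", {
  # canonical example: unit triad rotated 90 deg about z then shifted
  ref <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  R0 <- rot_z(pi / 2); t0 <- c(1, 2, 3)
  obs <- sweep(ref %*% t(R0), 2, -t0)
  fit <- fit_rigid_transform(ref, obs)
  expect_lt(max(abs(fit$pose$R - R0)), 1e-12)
  expect_lt(max(abs(fit$pose$t - t0)), 1e-12)
  expect_lt(fit$rms, 1e-12)

  # identity case
  fit0 <- fit_rigid_transform(ref, ref)
  expect_lt(max(abs(fit0$pose$R - diag(3))), 1e-12)
  expect_lt(max(abs(fit0$pose$t)), 1e-12)

  # random transforms, random clouds
  set.seed(101)
  for (q in 1:50) {
    n <- sample(3:8, 1)
    ref <- matrix(rnorm(3 * n, 0, 80), n, 3)
    p0 <- random_pose()
    obs <- pose_apply(p0, ref)
    fit <- fit_rigid_transform(ref, obs)
    expect_lt(max(abs(fit$pose$R - p0$R)), 1e-10)
    expect_lt(max(abs(fit$pose$t - p0$t)), 1e-9)
    expect_true(is_valid_rotation(fit$pose$R))
  }
})

test_that("rigid transform fit rejects degenerate input", {
  line <- cbind(seq(0, 100, length.out = 5), 0, 0)
  expect_error(fit_rigid_transform(line, line), "collinear")
  two <- matrix(rnorm(6), 2, 3)
  expect_error(fit_rigid_transform(two, two), "at least 3")
})

test_that("noisy pose fit stays accurate at survey scale", {
  # 100 mm triad, isotropic 0.5 mm noise: rotation error well under 1 deg
  set.seed(7)
  ref <- rbind(c(0, 0, 0), c(100, 0, 0), c(0, 100, 0), c(0, 0, 100))
  worst <- 0; rms_acc <- numeric(0)
  for (q in 1:1000) {
    p0 <- random_pose()
    obs <- pose_apply(p0, ref) + matrix(rnorm(12, 0, 0.5), 4, 3)
    fit <- fit_rigid_transform(ref, obs)
    dR <- t(p0$R) %*% fit$pose$R
    angle <- acos(min(1, (sum(diag(dR)) - 1) / 2)) * 180 / pi
    worst <- max(worst, angle)
    rms_acc <- c(rms_acc, fit$rms)
  }
  expect_lt(worst, 1)
  expect_gt(mean(rms_acc), 0.2)  # residual reflects the injected noise scale
  expect_lt(mean(rms_acc), 0.8)
})

test_that("pivot calibration recovers a known tip", {
  set.seed(3)
  tip <- c(15, -8, -140); piv <- c(300, 250, 120)
  Rs <- random_rotations(60)
  poses <- lapply(1:60, function(q)
    pose(Rs[, , q], piv - as.numeric(Rs[, , q] %*% tip), check = FALSE))
  pm <- pivot_calibrate(as_pose_series(poses))
  expect_lt(max(abs(pm$tip_offset - tip)), 1e-9)
  expect_lt(max(abs(pm$pivot_point - piv)), 1e-9)
  expect_lt(pm$rms, 1e-9)

  # noisy: 0.2 mm translational jitter over 200 poses -> tip within 0.5 mm
  Rs <- random_rotations(200)
  poses <- lapply(1:200, function(q)
    pose(Rs[, , q],
         piv - as.numeric(Rs[, , q] %*% tip) + rnorm(3, 0, 0.2),
         check = FALSE))
  pm2 <- pivot_calibrate(as_pose_series(poses))
  expect_lt(sqrt(sum((pm2$tip_offset - tip)^2)), 0.5)
  expect_gt(pm2$rms, 0)

  # pure translation: offset unobservable
  trans <- lapply(1:30, function(q) pose(diag(3), rnorm(3, 0, 50),
                                         check = FALSE))
  expect_error(pivot_calibrate(as_pose_series(trans)), "diversity")
  expect_error(pivot_calibrate(as_pose_series(poses[1:5])), ">= 10")
})

test_that("landmark registration and virtual reconstruction are inverse", {
  set.seed(5)
  pointer <- structure(list(tip_offset = c(10, 0, -120)),
                       class = "pointer_model")
  for (q in 1:20) {
    ppose <- random_pose(); cpose <- random_pose()
    tip_lab <- pointer_tip(pointer, ppose)
    local <- register_landmark(pointer, ppose, cpose)
    # direct matrix oracle: R'(tip - d)
    expect_equal(as.numeric(local),
                 as.numeric(t(cpose$R) %*% (tip_lab - cpose$t)),
                 tolerance = 1e-12)
    # reconstruct in the same frame: back to the lab tip position
    expect_equal(reconstruct_virtual_marker(as.numeric(local), cpose),
                 tip_lab, tolerance = 1e-9)
  }
  # identity cluster pose: local vector equals the lab tip
  idp <- pose()
  expect_equal(as.numeric(register_landmark(pointer, idp, idp)),
               pointer$tip_offset)
})

test_that("virtual markers are equivariant under rigid cluster motion", {
  set.seed(9)
  local <- c(30, -40, 25)
  for (q in 1:20) {
    base <- random_pose(); move <- random_pose()
    moved <- pose_compose(move, base)
    v1 <- reconstruct_virtual_marker(local, base)
    v2 <- reconstruct_virtual_marker(local, moved)
    expect_equal(v2, pose_apply(move, v1), tolerance = 1e-9)
  }
  expect_equal(reconstruct_virtual_marker(local, pose()), local)
})

test_that("averaging the registration window suppresses noise", {
  set.seed(13)
  pointer <- structure(list(tip_offset = c(0, 0, -150)),
                       class = "pointer_model")
  truth <- c(25, 40, -10)
  scatter <- function(n_frames) {
    errs <- replicate(200, {
      poses <- lapply(seq_len(n_frames), function(q) {
        R <- rot_z(0.3 * q / n_frames) %*% rot_x(0.4)
        pose(R, truth - as.numeric(R %*% pointer$tip_offset) +
               rnorm(3, 0, 0.5), check = FALSE)
      })
      cl <- as_pose_series(lapply(seq_len(n_frames),
                                  function(q) pose(diag(3), c(0, 0, 0),
                                                   check = FALSE)))
      v <- register_landmark(pointer, as_pose_series(poses), cl)
      sqrt(sum((v - truth)^2))
    })
    mean(errs)
  }
  e1 <- scatter(1); e50 <- scatter(50)
  expect_lt(e50, e1 / 2)   # ~1/sqrt(50) in expectation
})
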