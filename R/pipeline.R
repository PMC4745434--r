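#' End-to-end processing pipelines
#'
#' High-level drivers: anatomical calibration of a subject from the static,
#' pivot and pointer-registration trials; per-trial joint angles for either
#' protocol; and the two-protocol repeatability comparison over a whole
#' study.
#'
#' @name pipeline
NULL

mean_rotation <- function(Rs) {
  M <- apply(Rs, c(1, 2), mean)
  sv <- svd(M)
  R <- sv$u %*% t(sv$v)
  if (det(R) < 0) R <- sv$u %*% diag(c(1, 1, -1)) %*% t(sv$v)
  R
}

#' Anatomical calibration of one subject (6DOF protocol)
#'
#' Establishes, from the calibration trials: the reference geometry of each
#' segment cluster (static-trial mean marker positions), the pointer tip
#' offset (pivot calibration), every landmark's constant position vector in
#' its cluster technical frame (pointer registration averaged over the
#' static window), the Davis hip joint centre, and the neutral foot
#' anatomical frame expressed in the foot technical frame.
#'
#' @param static [marker_trajectory_set()] of the neutral static trial
#'   (all cluster markers).
#' @param pivot [marker_trajectory_set()] of the pointer pivot trial.
#' @param registration named list landmark -> mts containing pointer and
#'   cluster markers with the tip on the landmark.
#' @param config a [marker_set_config()] with `model = "isb6dof"`.
#' @return Object of class `anatomical_calibration`: `cluster_refs`,
#'   `pointer` (pointer model + reference geometry), `landmarks` (segment
#'   -> landmark -> local 3-vector), `landmark_rms`, `hjc`, `foot_offset`.
#' @export
calibrate_subject <- function(static, pivot, registration, config) {
  stopifnot(inherits(config, "marker_set_config"))
  if (config$model != "isb6dof")
    stop("anatomical calibration applies to the isb6dof protocol")
  for (seg in names(config$clusters)) {
    miss <- setdiff(config$clusters[[seg]], static$labels)
    if (length(miss))
      stop("static trial is missing cluster '", seg, "' marker(s): ",
           paste(miss, collapse = ", "))
  }
  cluster_refs <- lapply(config$clusters, function(lab)
    cluster_reference(static, lab))
  # pointer technical frame anchored at its first pivot-trial observation
  pl <- config$pointer_labels
  miss <- setdiff(pl, pivot$labels)
  if (length(miss))
    stop("pivot trial is missing pointer marker(s): ",
         paste(miss, collapse = ", "))
  f1 <- which(rowSums(!sapply(pl, function(l) pivot$valid[[l]])) == 0)[1]
  if (is.na(f1)) stop("no pivot frame with all pointer markers valid")
  pointer_ref <- t(vapply(pl, function(l) pivot$pos[[l]][f1, ], numeric(3)))
  pointer_poses <- fit_pose_series(pivot, pl, pointer_ref)
  pointer <- pivot_calibrate(pointer_poses)
  pointer$reference <- pointer_ref
  pointer$labels <- pl

  landmarks <- lapply(config$clusters, function(...) list())
  landmark_rms <- list()
  for (lm in names(registration)) {
    seg <- config$landmarks[[lm]]
    if (is.null(seg))
      stop("registration trial for unknown landmark '", lm, "'")
    trial <- registration[[lm]]
    pp <- fit_pose_series(trial, pl, pointer_ref)
    cp <- fit_pose_series(trial, config$clusters[[seg]],
                          cluster_refs[[seg]])
    v <- register_landmark(pointer, pp, cp)
    landmarks[[seg]][[lm]] <- as.numeric(v)
    landmark_rms[[lm]] <- stats::sd(apply(
      vapply(which(pp$valid & cp$valid), function(f)
        register_landmark(pointer, pose_at(pp, f), pose_at(cp, f)),
        numeric(3)), 2, function(r) sqrt(sum((r - v)^2))))
  }
  for (seg in names(.isb_landmarks)) {
    miss <- setdiff(.isb_landmarks[[seg]],
                    unlist(lapply(landmarks, names)))
    if (length(miss))
      stop("calibration incomplete: segment '", seg,
           "' lacks landmark(s) ", paste(miss, collapse = ", "))
  }
  a <- config$anthropometrics
  hjc <- davis_hip_joint_centre(a$leg_length, a$inter_asis,
                                a$asis_trochanter_offset %||% NULL,
                                a$marker_radius, side = "right")
  # neutral foot frame: shank anatomical frame during the static trial,
  # expressed in the foot technical frame
  static_poses <- lapply(names(config$clusters), function(seg)
    fit_pose_series(static, config$clusters[[seg]], cluster_refs[[seg]]))
  names(static_poses) <- names(config$clusters)
  lmk_static <- .reconstruct_landmarks(static_poses, landmarks, static$rate)
  frames_static <- build_isb_frames(lmk_static, hjc)
  fs <- frames_static$shank
  ft <- static_poses$foot
  ok <- which(fs$valid & ft$valid)
  if (!length(ok)) stop("no static frame with shank and foot poses valid")
  offs <- lapply(ok, function(f)
    foot_neutral_offset(pose_at(fs, f), pose_at(ft, f)))
  foot_offset <- pose(mean_rotation(simplify2array(lapply(offs,
                                                          `[[`, "R"))),
                      rowMeans(vapply(offs, `[[`, numeric(3), "t")),
                      check = FALSE)
  structure(list(cluster_refs = cluster_refs, pointer = pointer,
                 landmarks = landmarks, landmark_rms = landmark_rms,
                 hjc = hjc, foot_offset = foot_offset),
            class = "anatomical_calibration")
}

.reconstruct_landmarks <- function(cluster_poses, landmarks, rate) {
  pos <- list(); valid <- list()
  for (seg in names(landmarks)) {
    for (lm in names(landmarks[[seg]])) {
      r <- reconstruct_virtual_marker(landmarks[[seg]][[lm]],
                                      cluster_poses[[seg]])
      pos[[lm]] <- r$pos; valid[[lm]] <- r$valid
    }
  }
  marker_trajectory_set(pos, rate, valid)
}

#' Joint angles of one dynamic trial, 6DOF protocol
#'
#' Pose-fits every cluster, reconstructs the calibrated virtual landmarks,
#' builds the ISB anatomical frames (foot by its neutral-position
#' definition) and decomposes the 12 clinical rotations; detected or
#' supplied foot-strike events then cut and 101-point-normalise each gait
#' cycle.
#'
#' @param trial dynamic [marker_trajectory_set()].
#' @param calibration an [calibrate_subject()] result.
#' @param config the `isb6dof` [marker_set_config()].
#' @param events foot-strike frames (>= 2); `NULL` to detect from the foot
#'   cluster centroid vs the reconstructed ASIS midpoint.
#' @param cutoff Butterworth cutoff in Hz applied to marker trajectories
#'   before pose fitting; `NULL` disables filtering.
#' @param lab_frame reference frame for pelvis angles (default identity).
#' @return List of class `trial_angles`: `curves`
#'   ([compute_joint_angles()] result), `cycles` (list of 101 x 12
#'   `gait_cycle`), `events`, `frames`, `landmarks`.
#' @export
trial_angles_isb <- function(trial, calibration, config, events = NULL,
                             cutoff = 6, lab_frame = pose()) {
  stopifnot(inherits(calibration, "anatomical_calibration"))
  if (!is.null(cutoff)) trial <- filter_trajectories(trial, cutoff)
  cluster_poses <- lapply(names(config$clusters), function(seg)
    fit_pose_series(trial, config$clusters[[seg]],
                    calibration$cluster_refs[[seg]]))
  names(cluster_poses) <- names(config$clusters)
  lmk <- .reconstruct_landmarks(cluster_poses, calibration$landmarks,
                                trial$rate)
  frames <- build_isb_frames(lmk, calibration$hjc,
                             foot_tech = cluster_poses$foot,
                             foot_offset = calibration$foot_offset)
  curves <- compute_joint_angles(frames, lab_frame, rate = trial$rate)
  if (is.null(events)) {
    heel <- Reduce(`+`, trial$pos[config$clusters$foot]) /
      length(config$clusters$foot)
    pel <- (lmk$pos[["RASIS"]] + lmk$pos[["LASIS"]]) / 2
    events <- detect_foot_strikes(heel, pel, trial$rate)
  }
  cycles <- .cut_cycles(curves, events)
  structure(list(curves = curves, cycles = cycles, events = events,
                 frames = frames, landmarks = lmk,
                 cluster_rms = lapply(cluster_poses, `[[`, "rms")),
            class = "trial_angles")
}

#' Joint angles of one dynamic trial, conventional (Helen Hayes) protocol
#'
#' @param trial dynamic [marker_trajectory_set()] with the conventional
#'   marker complement.
#' @param config the `hh` [marker_set_config()].
#' @inheritParams trial_angles_isb
#' @return Same structure as [trial_angles_isb()].
#' @export
trial_angles_hh <- function(trial, config, events = NULL, cutoff = 6,
                            lab_frame = pose()) {
  stopifnot(inherits(config, "marker_set_config"))
  if (config$model != "hh") stop("config is not a conventional-model config")
  if (!is.null(cutoff)) trial <- filter_trajectories(trial, cutoff)
  a <- config$anthropometrics
  hjc <- davis_hip_joint_centre(a$leg_length, a$inter_asis,
                                a$asis_trochanter_offset %||% NULL,
                                a$marker_radius, side = "right")
  frames <- build_hh_frames(trial, hjc, config)
  curves <- compute_joint_angles(frames, lab_frame, rate = trial$rate)
  if (is.null(events)) {
    lab <- config$hh_labels
    pel <- (trial$pos[[lab[["RASIS"]]]] + trial$pos[[lab[["LASIS"]]]]) / 2
    events <- detect_foot_strikes(trial$pos[[lab[["RHEE"]]]], pel,
                                  trial$rate)
  }
  cycles <- .cut_cycles(curves, events)
  structure(list(curves = curves, cycles = cycles, events = events,
                 frames = frames),
            class = "trial_angles")
}

.cut_cycles <- function(curves, events) {
  events <- sort(as.integer(events))
  if (length(events) < 2L)
    stop("need at least two foot-strike events for one full gait cycle")
  cycles <- list()
  for (k in seq_len(length(events) - 1L))
    cycles[[k]] <- normalize_gait_cycle(curves, events[k], events[k + 1L],
                                        cycle_index = k)
  cycles
}

## --- study-level processing ------------------------------------------------

#' Read a generated study back from disk
#'
#' @param dir directory holding a `manifest.yaml` written by
#'   [generate_study()].
#' @return In-memory study list (same shape as [generate_study()] output,
#'   plus `manifest`).
#' @export
read_study <- function(dir) {
  mpath <- file.path(dir, "manifest.yaml")
  if (!file.exists(mpath)) stop("no manifest.yaml under ", dir)
  man <- yaml::read_yaml(mpath)
  rd <- function(rel) {
    p <- file.path(dir, rel)
    if (man$format == "c3d") read_c3d(p) else
      read_csv_trajectories(p, man$rate)
  }
  subjects <- lapply(man$subjects, function(e) {
    reg <- lapply(e$registration, rd)
    trials <- lapply(e$dynamic, function(d)
      list(markers = rd(d$trial),
           truth_angles = read_angle_curves(file.path(dir, d$truth)),
           events = as.integer(d$events)))
    subj <- synthetic_subject(scale = e$anthropometrics$leg_length / 860,
                              wand_misalignment_deg =
                                man$wand_misalignment_deg %||% 0)
    list(subject = subj,
         calibration = list(static = rd(e$static), pivot = rd(e$pivot),
                            registration = reg),
         trials = trials)
  })
  list(subjects = subjects, manifest = man,
       config = simulation_config(
         n_subjects = man$n_subjects, n_trials = man$n_trials,
         rate = man$rate, stride_s = man$stride_s,
         sigma_trial = man$sigma_trial, tau_subject = man$tau_subject,
         marker_noise_sd = man$marker_noise_sd,
         wand_misalignment_deg = man$wand_misalignment_deg %||% 0,
         seed = man$seed))
}

#' Process a whole study under one or both protocols
#'
#' Calibrates each subject (6DOF), computes the angle cycles of every
#' dynamic trial under the requested protocols using the stored ground-
#' truth events, and returns the nested cycle lists ready for
#' [variability_report()].
#'
#' @param study in-memory study ([generate_study()]/[read_study()] output).
#' @param protocols subset of `c("isb6dof", "hh")`.
#' @param cutoff Butterworth cutoff (Hz) or `NULL`.
#' @param use_truth_events use the stored events (default) instead of
#'   detection.
#' @return List per protocol: subject -> list of `gait_cycle` (one per
#'   trial, first cycle of each trial).
#' @export
process_study <- function(study, protocols = c("isb6dof", "hh"),
                          cutoff = 6, use_truth_events = TRUE) {
  protocols <- match.arg(protocols, several.ok = TRUE)
  out <- stats::setNames(vector("list", length(protocols)), protocols)
  for (j in seq_along(study$subjects)) {
    sj <- study$subjects[[j]]
    id <- sprintf("S%02d", j)
    cfg_isb <- synthetic_config(sj$subject, "isb6dof")
    cfg_hh <- synthetic_config(sj$subject, "hh")
    calib <- if ("isb6dof" %in% protocols)
      calibrate_subject(sj$calibration$static, sj$calibration$pivot,
                        sj$calibration$registration, cfg_isb) else NULL
    for (i in seq_along(sj$trials)) {
      tr <- sj$trials[[i]]
      ev <- if (use_truth_events) tr$events else NULL
      if ("isb6dof" %in% protocols) {
        ta <- trial_angles_isb(tr$markers, calib, cfg_isb, events = ev,
                               cutoff = cutoff)
        out$isb6dof[[id]] <- c(out$isb6dof[[id]], ta$cycles[1])
      }
      if ("hh" %in% protocols) {
        ta <- trial_angles_hh(tr$markers, cfg_hh, events = ev,
                              cutoff = cutoff)
        out$hh[[id]] <- c(out$hh[[id]], ta$cycles[1])
      }
    }
  }
  out
}
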