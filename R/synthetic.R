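#' Synthetic multi-subject gait data by forward kinematics
#'
#' Generates ground-truth marker trajectories for both marker sets
#' (technical clusters + pointer landmark registrations for the 6DOF
#' protocol; skin and wand markers for the conventional model) by driving
#' a rigid articulated lower limb with smooth, periodic, gait-like joint
#' angle templates.  Intertrial and between-subject variation, isotropic
#' marker noise, cycle-locked soft-tissue artefact and a thigh-wand
#' frontal-plane misalignment are all controllable, so the full analysis
#' pipeline can be validated end to end against known angles.
#'
#' @name synthetic_gait
NULL

## --- gait angle templates --------------------------------------------------
## truncated Fourier series per rotation (degrees, cycle fraction t in [0,1]),
## loosely shaped on normative adult gait (sagittal knee peak ~60 deg in
## swing, hip flexion maximal at initial contact); coefficients are fixture
## values, not claims about any particular population.
.gait_template_coef <- list(
  pelvis_tilt = c(6.75, 0, 0, -0.75, 0),
  pelvis_obliquity = c(0.0168, 1.241, 1.5532, -0.0812, -0.1405),
  pelvis_rotation = c(0, 5, 0, 0, 0),
  hip_flex_ext = c(11.4, 20.7859, -2.8215, -2.7652, -1.6207, 0.2141, 2.021),
  hip_abd_add = c(0.8453, 1.0633, 4.9812, -0.9504, -1.2042, -0.4677, 0.3387),
  hip_int_ext = c(0, -2, 3, 0, 0),
  knee_flex_ext = c(20.1896, 1.5977, -20.083, -14.8344, 4.152, -1.3987,
                    4.7989, -0.2283, -0.6544),
  knee_var_valg = c(0, 0, 2, 0, 0),
  knee_int_ext = c(1.5582, 0.0062, -1.6054, -1.0445, 0.4862, -0.0162,
                   0.2099),
  ankle_dor_pla = c(-0.2943, -0.6899, 6.0417, 0.6194, -6.6917, -1.8318,
                    1.3974, 1.9722, -1.8772),
  ankle_inv_ev = c(0.4418, -2, 2.8623, 1.1548, -2.227),
  ankle_abd_add = c(0, 0, -1.5, 0, 0))

#' Template joint-angle curves
#'
#' Evaluates the built-in periodic gait templates.
#'
#' @param t numeric vector of cycle fractions (any real; periodic).
#' @return length(t) x 12 matrix (degrees), columns [rotation_labels()].
#' @export
gait_template_curves <- function(t) {
  out <- sapply(rotation_labels(), function(l) {
    cf <- .gait_template_coef[[l]]
    K <- (length(cf) - 1L) / 2L
    y <- rep(cf[1], length(t))
    for (k in seq_len(K))
      y <- y + cf[2 * k] * cos(2 * pi * k * t) +
        cf[2 * k + 1] * sin(2 * pi * k * t)
    y
  })
  if (length(t) == 1L) out <- matrix(out, 1L, 12L,
                                     dimnames = list(NULL, rotation_labels()))
  out
}

## --- subject ---------------------------------------------------------------

#' Synthetic subject: rigid segment geometry and marker placement
#'
#' All local positions are expressed in the segment anatomical frames
#' (X anterior, Y up, Z right; neutral stance = all frames lab-aligned).
#' The true hip joint centre is placed exactly at the Davis regression
#' prediction for the subject's anthropometrics, so landmark-based
#' reconstruction is exact on noise-free data.
#'
#' @param scale global geometric scale factor (stature variation).
#' @param wand_misalignment_deg rotation of the thigh wand marker about the
#'   femur long axis, degrees (frontal-plane misalignment; 0 = wand exactly
#'   in the frontal plane).
#' @return Object of class `synthetic_subject`.
#' @export
synthetic_subject <- function(scale = 1, wand_misalignment_deg = 0) {
  if (!is.finite(scale) || scale <= 0) stop("scale must be > 0")
  s <- scale
  thigh <- 420 * s; shank <- 400 * s
  anthro <- list(leg_length = 860 * s, inter_asis = 240 * s,
                 knee_width = 90 * s, ankle_width = 70 * s,
                 marker_radius = 0)
  hjc <- davis_hip_joint_centre(anthro$leg_length, anthro$inter_asis,
                                marker_radius = 0, side = "right")
  landmarks <- list(
    pelvis = list(RASIS = c(0, 0, 120) * s, LASIS = c(0, 0, -120) * s,
                  RPSIS = c(-130, 0, 50) * s, LPSIS = c(-130, 0, -50) * s),
    femur = list(RLEPI = c(0, -thigh, 45 * s), RMEPI = c(0, -thigh, -45 * s)),
    shank = list(RLCON = c(0, -20 * s, 40 * s), RMCON = c(0, -20 * s, -40 * s),
                 RLMAL = c(0, -shank, 35 * s), RMMAL = c(0, -shank, -35 * s)),
    foot = list())
  clusters <- list(
    pelvis = list(PELC1 = c(-150, 20, 0) * s, PELC2 = c(-120, 90, 60) * s,
                  PELC3 = c(-115, 85, -65) * s),
    femur = list(THIC1 = c(20, -180, 70) * s, THIC2 = c(-30, -250, 80) * s,
                 THIC3 = c(40, -285, 72) * s),
    shank = list(SHAC1 = c(30, -120, 55) * s, SHAC2 = c(-20, -200, 65) * s,
                 SHAC3 = c(35, -265, 58) * s),
    foot = list(FOTC1 = c(60, -40, -20) * s, FOTC2 = c(120, -50, 25) * s,
                FOTC3 = c(40, -55, 30) * s))
  wand_th <- wand_misalignment_deg * pi / 180
  hh <- list(
    pelvis = list(HH_RASIS = landmarks$pelvis$RASIS,
                  HH_LASIS = landmarks$pelvis$LASIS,
                  HH_SACR = c(-140, 0, 0) * s),
    femur = list(HH_RTHI = as.numeric(rot_y(wand_th) %*% (c(0, -200, 100) * s)),
                 HH_RKNE = landmarks$femur$RLEPI),
    shank = list(HH_RTIB = c(0, -200, 90) * s,
                 HH_RANK = landmarks$shank$RLMAL),
    foot = list(HH_RHEE = c(-60, -70, 0) * s, HH_RTOE = c(160, -70, 0) * s))
  pointer <- list(
    markers = list(PTR1 = c(0, 0, 0), PTR2 = c(100, 0, 0),
                   PTR3 = c(0, 80, 0), PTR4 = c(55, 45, 60)),
    tip_offset = c(20, -10, -150))
  structure(list(scale = s, thigh_length = thigh, shank_length = shank,
                 hip_height = 980 * s, anthropometrics = anthro,
                 hjc_local = hjc$position, landmarks = landmarks,
                 clusters = clusters, hh = hh, pointer = pointer,
                 wand_misalignment_deg = wand_misalignment_deg),
            class = "synthetic_subject")
}

#' Marker-set configuration matching [synthetic_subject()]
#' @param subject a `synthetic_subject`.
#' @param model `"isb6dof"` or `"hh"`.
#' @return A [marker_set_config()].
#' @export
synthetic_config <- function(subject, model = c("isb6dof", "hh")) {
  model <- match.arg(model)
  if (model == "isb6dof") {
    seg_of <- unlist(lapply(names(subject$landmarks), function(sg)
      stats::setNames(rep(sg, length(subject$landmarks[[sg]])),
                      names(subject$landmarks[[sg]]))))
    marker_set_config(
      model = "isb6dof",
      clusters = lapply(subject$clusters, names),
      landmarks = seg_of,
      pointer_labels = names(subject$pointer$markers),
      anthropometrics = subject$anthropometrics)
  } else {
    hh_all <- unlist(subject$hh, recursive = FALSE)
    names(hh_all) <- unlist(lapply(subject$hh, names))
    marker_set_config(
      model = "hh",
      hh_labels = stats::setNames(names(hh_all),
                                  sub("^HH_", "", names(hh_all))),
      anthropometrics = subject$anthropometrics)
  }
}

## --- simulation configuration ----------------------------------------------

#' Simulation configuration
#'
#' Defaults emulate the study design the package is validated against:
#' four able-bodied subjects, three gait trials each, 100 Hz capture, 1 s
#' stride; intertrial angle dispersion sigma = 1 degree, between-subject
#' dispersion tau = 3 degrees; 0.5 mm isotropic marker noise; soft-tissue
#' artefact and wand misalignment off.
#'
#' @param n_subjects,n_trials study shape.
#' @param rate sampling frequency, Hz.
#' @param stride_s stride duration, s.
#' @param stride_length_mm stride length (pelvis advance per cycle), mm.
#' @param sigma_trial intertrial angle SD, degrees (>= 0).
#' @param tau_subject between-subject angle SD, degrees (>= 0).
#' @param marker_noise_sd isotropic marker noise SD, mm (>= 0).
#' @param sta_amplitude named list/vector segment -> soft-tissue-artefact
#'   amplitude (mm), cycle-locked; empty = off.
#' @param wand_misalignment_deg thigh-wand frontal-plane misalignment,
#'   degrees.
#' @param seed RNG seed (integer), recorded in every output.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(n_subjects = 4, n_trials = 3, rate = 100,
                              stride_s = 1.0, stride_length_mm = 1300,
                              sigma_trial = 1.0, tau_subject = 3.0,
                              marker_noise_sd = 0.5,
                              sta_amplitude = list(),
                              wand_misalignment_deg = 0, seed = 20150129) {
  bad <- c(n_subjects < 1, n_trials < 1, rate <= 0, stride_s <= 0,
           sigma_trial < 0, tau_subject < 0, marker_noise_sd < 0)
  fields <- c("n_subjects", "n_trials", "rate", "stride_s", "sigma_trial",
              "tau_subject", "marker_noise_sd")
  if (any(bad))
    stop("invalid simulation config field(s): ",
         paste(fields[bad], collapse = ", "))
  structure(list(n_subjects = as.integer(n_subjects),
                 n_trials = as.integer(n_trials), rate = rate,
                 stride_s = stride_s, stride_length_mm = stride_length_mm,
                 sigma_trial = sigma_trial, tau_subject = tau_subject,
                 marker_noise_sd = marker_noise_sd,
                 sta_amplitude = as.list(sta_amplitude),
                 wand_misalignment_deg = wand_misalignment_deg,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

## moment-exact dispersion designs: a random permutation of fixed values
## whose sample SD is exactly 1, so the injected dispersion parameter is
## realised, not merely expected, in every generated study (with n as small
## as 3 trials the expected sample SD of i.i.d. Gaussian draws is only
## c4(n) ~ 0.89 of the population value).
.unit_sd_design <- function(n) {
  if (n < 2L) return(rep(0, n))
  q <- stats::qnorm((seq_len(n) - 0.375) / (n + 0.25))
  q <- q - mean(q)
  q / stats::sd(q)
}

.study_effects <- function(config) {
  set.seed(config$seed %% .Machine$integer.max)
  ns <- config$n_subjects; nt <- config$n_trials
  subj_design <- .unit_sd_design(ns)
  trial_design <- .unit_sd_design(nt)
  subject_eff <- matrix(0, ns, 12)
  trial_eff <- array(0, c(ns, nt, 12))
  for (r in 1:12) {
    subject_eff[, r] <- config$tau_subject *
      sample(subj_design) * sample(c(-1, 1), 1)
    for (j in seq_len(ns)) {
      m <- stats::rnorm(1, 0, config$sigma_trial / sqrt(nt))
      trial_eff[j, , r] <- m + config$sigma_trial * sample(trial_design)
    }
  }
  list(subject = subject_eff, trial = trial_eff)
}

#' Ground-truth angle curves for one subject and trial
#'
#' Template curves plus a constant per-rotation subject effect (dispersion
#' `tau_subject` across subjects) and trial effect (within-subject
#' dispersion exactly `sigma_trial`).  Deterministic in `config$seed`.
#'
#' @param config a [simulation_config()].
#' @param subject subject index (1-based).
#' @param trial trial index (1-based).
#' @param t cycle fractions to evaluate (default the 101-point grid).
#' @return length(t) x 12 matrix (degrees) with attribute `offsets`
#'   (the 12 constant offsets applied to the template).
#' @export
generate_angle_curves <- function(config, subject, trial,
                                  t = seq(0, 1, length.out = 101L)) {
  stopifnot(inherits(config, "simulation_config"),
            subject >= 1, subject <= config$n_subjects,
            trial >= 1, trial <= config$n_trials)
  eff <- .study_effects(config)
  offs <- eff$subject[subject, ] + eff$trial[subject, trial, ]
  out <- sweep(gait_template_curves(t), 2, offs, `+`)
  attr(out, "offsets") <- stats::setNames(offs, rotation_labels())
  out
}

## --- forward kinematics ----------------------------------------------------

.raw_from_clinical <- function(angles) sweep(angles, 2, .rotation_signs, `*`)

#' Forward kinematics: marker and landmark trajectories from angle curves
#'
#' Composes the segment chain pelvis -> femur -> shank -> foot with the
#' same z-x-y Cardan sequence and sign conventions used by
#' [compute_joint_angles()], then emits every cluster marker, skin/wand
#' marker and true anatomical landmark in lab coordinates.
#'
#' @param subject a [synthetic_subject()].
#' @param angles n x 12 clinical angle matrix (degrees).
#' @param t cycle fraction per frame (length n; drives pelvis translation).
#' @param rate sampling frequency, Hz.
#' @param stride_length_mm pelvis advance per cycle, mm.
#' @param lab_frame [pose()] of the lab in which output is expressed
#'   (default identity; any rigid transform leaves joint angles unchanged).
#' @return List: `markers` ([marker_trajectory_set()], clusters + HH +
#'   pointerless), `landmarks` (mts of true landmark positions),
#'   `segment_poses` (true pose series per segment).
#' @export
forward_kinematics <- function(subject, angles, t, rate,
                               stride_length_mm = 1300,
                               lab_frame = pose()) {
  stopifnot(inherits(subject, "synthetic_subject"),
            nrow(angles) == length(t), ncol(angles) == 12L)
  raw <- .raw_from_clinical(angles)
  if (any(abs(raw[, c(2, 5, 8, 11)]) > 89))
    stop("prescribed curves reach the gimbal range (|middle angle| > 89)")
  nf <- length(t)
  segs <- c("pelvis", "femur", "shank", "foot")
  poses <- lapply(segs, function(s)
    list(R = array(NA_real_, c(3, 3, nf)), t = matrix(NA_real_, 3, nf),
         valid = rep(TRUE, nf)))
  names(poses) <- segs
  for (f in seq_len(nf)) {
    pel_o <- c(stride_length_mm * t[f],
               subject$hip_height + 15 * sin(4 * pi * t[f]),
               10 * sin(2 * pi * t[f]))
    p_pel <- pose_compose(lab_frame,
                          pose(cardan_compose(raw[f, 1:3]), pel_o,
                               check = FALSE))
    p_fem <- pose_compose(p_pel, pose(cardan_compose(raw[f, 4:6]),
                                      subject$hjc_local, check = FALSE))
    p_shk <- pose_compose(p_fem, pose(cardan_compose(raw[f, 7:9]),
                                      c(0, -subject$thigh_length, 0),
                                      check = FALSE))
    p_fot <- pose_compose(p_shk, pose(cardan_compose(raw[f, 10:12]),
                                      c(0, -subject$shank_length, 0),
                                      check = FALSE))
    ps <- list(pelvis = p_pel, femur = p_fem, shank = p_shk, foot = p_fot)
    for (s in segs) {
      poses[[s]]$R[, , f] <- ps[[s]]$R; poses[[s]]$t[, f] <- ps[[s]]$t
    }
  }
  poses <- lapply(poses, function(p) structure(p, class = "pose_series"))
  emit <- function(local_by_segment) {
    out <- list()
    for (s in names(local_by_segment)) {
      for (l in names(local_by_segment[[s]])) {
        loc <- local_by_segment[[s]][[l]]
        m <- matrix(NA_real_, nf, 3)
        for (f in seq_len(nf))
          m[f, ] <- as.numeric(poses[[s]]$R[, , f] %*% loc +
                                 poses[[s]]$t[, f])
        out[[l]] <- m
      }
    }
    out
  }
  marker_locals <- list()
  for (s in segs)
    marker_locals[[s]] <- c(subject$clusters[[s]], subject$hh[[s]])
  markers <- marker_trajectory_set(emit(marker_locals), rate)
  landmarks <- marker_trajectory_set(emit(subject$landmarks[
    vapply(subject$landmarks, length, integer(1)) > 0]), rate)
  list(markers = markers, landmarks = landmarks, segment_poses = poses)
}

#' Add measurement noise and soft-tissue artefact to marker data
#'
#' Adds (i) i.i.d. isotropic Gaussian noise of SD `marker_noise_sd` to
#' every valid sample and (ii) a cycle-locked sinusoidal displacement of
#' all markers of a segment (amplitude per segment via `sta_amplitude`,
#' direction anterior-superior, phase locked to the gait cycle) emulating
#' en-bloc cluster/skin motion relative to the bone.
#'
#' @param markers a [marker_trajectory_set()].
#' @param config a [simulation_config()].
#' @param t cycle fraction per frame (length `markers$n_frames`).
#' @param segment_of named character: marker label -> segment (labels
#'   absent from it get noise but no artefact).
#' @return A perturbed [marker_trajectory_set()].
#' @export
apply_artifacts <- function(markers, config, t,
                            segment_of = NULL) {
  x <- markers
  pos <- x$pos
  sta <- config$sta_amplitude
  dirn <- c(2, 1, 0) / sqrt(5)    # anterior-superior displacement
  for (l in x$labels) {
    seg <- if (!is.null(segment_of)) segment_of[[l]] else NULL
    if (!is.null(seg) && !is.null(sta[[seg]]) && sta[[seg]] != 0) {
      amp <- sta[[seg]]
      shift <- outer(amp * sin(2 * pi * t), dirn)
      pos[[l]] <- pos[[l]] + shift
    }
    if (config$marker_noise_sd > 0)
      pos[[l]] <- pos[[l]] + matrix(stats::rnorm(3 * x$n_frames, 0,
                                                 config$marker_noise_sd),
                                    x$n_frames, 3)
  }
  marker_trajectory_set(pos, x$rate, x$valid)
}

#' Marker label -> segment map for a synthetic subject
#' @param subject a [synthetic_subject()].
#' @return Named character vector.
#' @export
synthetic_segment_map <- function(subject) {
  segs <- names(subject$clusters)
  out <- character(0)
  for (s in segs) {
    lab <- c(names(subject$clusters[[s]]), names(subject$hh[[s]]))
    out <- c(out, stats::setNames(rep(s, length(lab)), lab))
  }
  out
}

## --- calibration trials ----------------------------------------------------

#' Synthetic static, pivot and pointer-registration trials
#'
#' Static trial: the neutral stack (all angles zero) held for
#' `n_frames` frames.  Pivot trial: the pointer pivoted about a fixed lab
#' point through a fan of orientations.  Registration trials: one short
#' trial per landmark with the pointer tip exactly on the landmark while
#' all clusters are visible.
#'
#' @param subject a [synthetic_subject()].
#' @param rate sampling frequency, Hz.
#' @param n_frames frames per static/registration trial.
#' @param noise_sd isotropic marker noise SD, mm.
#' @return List: `static` (mts), `pivot` (mts), `registration` (named list
#'   landmark -> mts of pointer + cluster markers).
#' @export
synthetic_calibration_trials <- function(subject, rate = 100, n_frames = 50,
                                         noise_sd = 0) {
  neutral <- matrix(0, n_frames, 12, dimnames = list(NULL, rotation_labels()))
  fk <- forward_kinematics(subject, neutral, rep(0, n_frames), rate,
                           stride_length_mm = 0)
  noisy <- function(m) if (noise_sd > 0)
    marker_trajectory_set(lapply(m$pos, function(p)
      p + matrix(stats::rnorm(length(p), 0, noise_sd), nrow(p), 3)),
      m$rate, m$valid) else m
  static <- noisy(marker_trajectory_set(
    c(fk$markers$pos, fk$landmarks$pos), rate))
  ptr <- subject$pointer
  pivot_point <- c(400, 300, 200)
  k <- 60
  ang <- seq(0, 2 * pi, length.out = k)
  piv_pos <- lapply(names(ptr$markers), function(l) {
    m <- matrix(NA_real_, k, 3)
    for (q in seq_len(k)) {
      R <- rot_z(0.6 * sin(ang[q])) %*% rot_x(0.6 * cos(ang[q])) %*%
        rot_y(0.3 * sin(2 * ang[q]))
      d <- pivot_point - as.numeric(R %*% ptr$tip_offset)
      m[q, ] <- as.numeric(R %*% ptr$markers[[l]] + d)
    }
    m
  })
  names(piv_pos) <- names(ptr$markers)
  pivot <- noisy(marker_trajectory_set(piv_pos, rate))
  lm_all <- unlist(unname(subject$landmarks), recursive = FALSE)
  # landmark lab positions in the neutral pose
  registration <- list()
  for (lm in names(lm_all)) {
    target <- fk$landmarks$pos[[lm]][1, ]
    regp <- lapply(names(ptr$markers), function(l) {
      m <- matrix(NA_real_, n_frames, 3)
      for (q in seq_len(n_frames)) {
        R <- rot_z(0.25 * sin(2 * pi * q / n_frames)) %*%
          rot_x(0.3 + 0.2 * cos(2 * pi * q / n_frames))
        d <- target - as.numeric(R %*% ptr$tip_offset)
        m[q, ] <- as.numeric(R %*% ptr$markers[[l]] + d)
      }
      m
    })
    names(regp) <- names(ptr$markers)
    cluster_pos <- lapply(fk$markers$pos[unlist(lapply(subject$clusters,
                                                       names))], identity)
    registration[[lm]] <- noisy(marker_trajectory_set(c(regp, cluster_pos),
                                                      rate))
  }
  list(static = static, pivot = pivot, registration = registration)
}

## --- study generation ------------------------------------------------------

#' Generate a complete synthetic study
#'
#' For each subject: one static (neutral) trial, one pointer pivot trial,
#' one pointer registration trial per landmark, and `n_trials` dynamic
#' gait trials carrying both marker sets, each spanning one full stride
#' with 0.2-cycle margins.  Ground-truth 101-point angle curves and event
#' frames are stored beside each trial.  With `dir` given, everything is
#' written to disk (C3D or CSV trials, CSV ground truth, YAML manifest
#' recording the seed); otherwise the dataset is returned in memory.
#'
#' @param config a [simulation_config()].
#' @param dir optional output directory.
#' @param format `"c3d"` or `"csv"` trial format (on-disk only).
#' @return Invisibly (or visibly when `dir` is `NULL`) a list with
#'   `subjects` (per subject: `subject`, `calibration` trials, `trials`
#'   with `markers`, `truth_angles`, `events`) and `config`.
#' @export
generate_study <- function(config = simulation_config(), dir = NULL,
                           format = c("c3d", "csv")) {
  format <- match.arg(format)
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed %% .Machine$integer.max)
  scales <- 1 + 0.05 * .unit_sd_design(config$n_subjects)
  margin <- 0.2
  nf <- as.integer(round((1 + 2 * margin) * config$rate * config$stride_s)) + 1L
  tt <- (seq_len(nf) - 1L) / (config$rate * config$stride_s) - margin
  ev <- c(which.min(abs(tt - 0)), which.min(abs(tt - 1)))
  subjects <- vector("list", config$n_subjects)
  seg_map_cache <- NULL
  for (j in seq_len(config$n_subjects)) {
    subj <- synthetic_subject(scale = scales[j],
                              wand_misalignment_deg =
                                config$wand_misalignment_deg)
    calib <- synthetic_calibration_trials(subj, rate = config$rate,
                                          noise_sd = config$marker_noise_sd)
    seg_map <- synthetic_segment_map(subj)
    trials <- vector("list", config$n_trials)
    for (i in seq_len(config$n_trials)) {
      ang <- generate_angle_curves(config, j, i, t = tt)
      fk <- forward_kinematics(subj, ang, tt, config$rate,
                               config$stride_length_mm)
      markers <- apply_artifacts(fk$markers, config, tt, seg_map)
      truth <- generate_angle_curves(config, j, i)
      colnames(truth) <- rotation_labels()
      trials[[i]] <- list(markers = markers, truth_angles = truth,
                          events = ev, landmarks = fk$landmarks)
    }
    subjects[[j]] <- list(subject = subj, calibration = calib,
                          trials = trials)
  }
  study <- list(subjects = subjects, config = config)
  if (is.null(dir)) return(study)
  write_study(study, dir, format)
  invisible(study)
}

#' Write a generated study to disk
#'
#' @param study result of [generate_study()].
#' @param dir output directory (created if needed).
#' @param format `"c3d"` or `"csv"`.
#' @return The manifest path, invisibly.
#' @export
write_study <- function(study, dir, format = c("c3d", "csv")) {
  format <- match.arg(format)
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create output directory: ", dir)
  wr <- function(mts, path) {
    if (format == "c3d") write_c3d(mts, path) else
      write_csv_trajectories(mts, path)
  }
  ext <- format
  cfg <- study$config
  manifest <- list(seed = cfg$seed, rate = cfg$rate,
                   stride_s = cfg$stride_s,
                   n_subjects = cfg$n_subjects, n_trials = cfg$n_trials,
                   sigma_trial = cfg$sigma_trial,
                   tau_subject = cfg$tau_subject,
                   marker_noise_sd = cfg$marker_noise_sd,
                   wand_misalignment_deg = cfg$wand_misalignment_deg,
                   format = format, subjects = list())
  for (j in seq_along(study$subjects)) {
    sj <- study$subjects[[j]]
    id <- sprintf("S%02d", j)
    sdir <- file.path(dir, id)
    dir.create(sdir, showWarnings = FALSE, recursive = TRUE)
    entry <- list(id = id,
                  anthropometrics = sj$subject$anthropometrics,
                  static = file.path(id, paste0("static.", ext)),
                  pivot = file.path(id, paste0("pivot.", ext)),
                  registration = list(), dynamic = list())
    wr(sj$calibration$static, file.path(dir, entry$static))
    wr(sj$calibration$pivot, file.path(dir, entry$pivot))
    for (lm in names(sj$calibration$registration)) {
      rel <- file.path(id, paste0("pointer_", lm, ".", ext))
      wr(sj$calibration$registration[[lm]], file.path(dir, rel))
      entry$registration[[lm]] <- rel
    }
    for (i in seq_along(sj$trials)) {
      tr <- sj$trials[[i]]
      rel <- file.path(id, sprintf("gait%02d.%s", i, ext))
      wr(tr$markers, file.path(dir, rel))
      truth_rel <- file.path(id, sprintf("gait%02d_truth.csv", i))
      write_angle_curves(tr$truth_angles, file.path(dir, truth_rel))
      entry$dynamic[[i]] <- list(trial = rel, truth = truth_rel,
                                 events = as.integer(tr$events))
    }
    manifest$subjects[[j]] <- entry
  }
  path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, path)
  invisible(path)
}
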