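#' Clinical joint angles from segment frames
#'
#' The relative orientation of each pair of adjacent anatomical frames is
#' decomposed into three Cardan angles in the z-x-y sequence: rotation
#' about the proximal mediolateral axis first (flexion/extension), then
#' about the floating anteroposterior axis (ab/adduction), then about the
#' distal longitudinal axis (internal/external rotation) -- the ordering
#' equivalent to the joint coordinate system.  Pelvis angles are taken
#' against the laboratory frame in the same sequence
#' (tilt, obliquity, rotation).
#'
#' Right-limb clinical sign conventions (positive directions): pelvis
#' anterior tilt, pelvis right side up, pelvis right side forward; hip and
#' knee flexion, adduction (knee varus), internal rotation; ankle
#' dorsiflexion, inversion, adduction.
#'
#' @name joint_kinematics
NULL

# raw z-x-y Cardan angles -> clinical signs, per rotation (see above)
.rotation_signs <- c(
  pelvis_tilt = -1, pelvis_obliquity = -1, pelvis_rotation = 1,
  hip_flex_ext = 1, hip_abd_add = 1, hip_int_ext = 1,
  knee_flex_ext = -1, knee_var_valg = 1, knee_int_ext = 1,
  ankle_dor_pla = 1, ankle_inv_ev = 1, ankle_abd_add = 1)

#' Sign and sequence conventions table
#'
#' @return data.frame with the 12 rotations, their joint, the Cardan slot
#'   (1 = first/flexion axis, 2 = middle, 3 = longitudinal) and the sign
#'   applied to the raw z-x-y angle to obtain the clinical angle.
#' @export
rotation_conventions <- function() {
  data.frame(rotation = rotation_labels(),
             joint = rep(c("pelvis", "hip", "knee", "ankle"), each = 3),
             cardan_slot = rep(1:3, 4),
             sequence = "zxy",
             sign = unname(.rotation_signs))
}

#' Relative rotation of a distal frame in a proximal frame
#'
#' @param proximal,distal [pose()] objects (or bare 3x3 rotations).
#' @return 3x3 rotation `t(R_proximal) %*% R_distal`.
#' @export
relative_rotation <- function(proximal, distal) {
  Rp <- if (inherits(proximal, "pose")) proximal$R else proximal
  Rd <- if (inherits(distal, "pose")) distal$R else distal
  assert_rotation(Rp); assert_rotation(Rd)
  t(Rp) %*% Rd
}

#' Unwrap an angle series across +/-180 degree jumps
#' @param x numeric vector, degrees (NA allowed).
#' @return unwrapped vector.
#' @export
unwrap_degrees <- function(x) {
  ok <- which(is.finite(x))
  if (length(ok) < 2L) return(x)
  y <- x
  offs <- 0
  for (q in 2:length(ok)) {
    d <- x[ok[q]] - x[ok[q - 1L]]
    if (d > 180) offs <- offs - 360 else if (d < -180) offs <- offs + 360
    y[ok[q]] <- x[ok[q]] + offs
  }
  y
}

#' Compute the 12 clinical rotations from segment frames
#'
#' @param frames a `segment_frame_set` with `pelvis`, `femur`, `shank` and
#'   `foot` pose series (from [build_isb_frames()] or [build_hh_frames()]).
#' @param lab_frame [pose()] of the reference (laboratory) frame used for
#'   the pelvis angles; default identity.
#' @param rate optional sampling rate (Hz), carried through.
#' @return Object of class `joint_angle_curves`: list with `angles`
#'   (frames x 12 matrix, degrees, columns [rotation_labels()]), `valid`
#'   (logical), `gimbal` (logical frames x 4, joints flagged near gimbal
#'   lock) and `rate`.
#' @export
compute_joint_angles <- function(frames, lab_frame = pose(), rate = NULL) {
  segs <- c("pelvis", "femur", "shank", "foot")
  miss <- setdiff(segs, names(frames))
  if (length(miss))
    stop("segment frame set is missing segment(s): ",
         paste(miss, collapse = ", "))
  nf <- length(frames$pelvis$valid)
  ang <- matrix(NA_real_, nf, 12,
                dimnames = list(NULL, rotation_labels()))
  joints <- c("pelvis", "hip", "knee", "ankle")
  gim <- matrix(FALSE, nf, 4, dimnames = list(NULL, joints))
  valid <- frames$pelvis$valid & frames$femur$valid &
    frames$shank$valid & frames$foot$valid
  Rlab <- lab_frame$R
  for (f in which(valid)) {
    rel <- list(
      pelvis = t(Rlab) %*% frames$pelvis$R[, , f],
      hip = t(frames$pelvis$R[, , f]) %*% frames$femur$R[, , f],
      knee = t(frames$femur$R[, , f]) %*% frames$shank$R[, , f],
      ankle = t(frames$shank$R[, , f]) %*% frames$foot$R[, , f])
    for (j in seq_along(joints)) {
      a <- cardan_decompose(rel[[j]], "zxy")
      gim[f, j] <- isTRUE(attr(a, "gimbal"))
      ang[f, (3 * j - 2):(3 * j)] <- as.numeric(a)
    }
  }
  ang <- sweep(ang, 2, .rotation_signs, `*`)
  ang <- apply(ang, 2, unwrap_degrees)
  if (nf == 1L) ang <- matrix(ang, 1L, 12,
                              dimnames = list(NULL, rotation_labels()))
  structure(list(angles = ang, valid = valid, gimbal = gim, rate = rate),
            class = "joint_angle_curves")
}
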