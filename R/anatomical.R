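#' Anatomical segment frames and the Davis hip joint centre
#'
#' Builds per-frame anatomical coordinate systems of the pelvis, femur,
#' shank and foot for two protocols: landmark-based frames following the
#' ISB convention (every segment axis defined by bony landmarks), and the
#' conventional Helen Hayes/Davis model in which thigh and shank frontal
#' planes are defined by wand markers.  All frames are right-handed with
#' X anterior, Y proximal (up) and Z pointing to the subject's right.
#'
#' @name anatomical
NULL

vnorm <- function(v) sqrt(sum(v^2))

unitv <- function(v, what = "axis") {
  n <- vnorm(v)
  if (!is.finite(n) || n < 1e-9)
    stop("degenerate geometry: zero-length ", what,
         " (coincident landmarks?)")
  v / n
}

frame_from_axes <- function(x, y, z, origin) {
  R <- cbind(x, y, z)
  assert_rotation(R, tol = 1e-6)
  # re-orthonormalise to numerical precision
  sv <- svd(R)
  pose(sv$u %*% t(sv$v), origin, check = FALSE)
}

## --- Davis hip joint centre ------------------------------------------------

#' Hip joint centre by the Davis (Newington) regression
#'
#' Linear anthropometric regression of the femoral head centre from leg
#' length and inter-ASIS distance, as published by Davis, Ounpuu, Tyburski
#' and Gage (1991), "A gait analysis data collection and reduction
#' technique", Human Movement Science 10:575-587.  Constants: theta = 28.4
#' degrees, beta = 18 degrees, C = 0.115 * leg_length - 15.3 mm; the
#' ASIS-to-trochanter distance defaults to its own published regression
#' 0.1288 * leg_length - 48.56 mm when not measured.
#'
#' @param leg_length leg length, mm (> 0).
#' @param inter_asis inter-ASIS distance, mm (> 0).
#' @param asis_trochanter_offset perpendicular ASIS-trochanter distance, mm;
#'   `NULL` for the regression default.
#' @param marker_radius marker radius, mm (>= 0; 0 for pointer-calibrated
#'   virtual landmarks).
#' @param side `"right"` or `"left"`.
#' @return Object of class `hjc`: list with `position` (3-vector in the
#'   pelvis anatomical frame, origin mid-ASIS, X anterior / Y up / Z right,
#'   mm) and `side`.
#' @export
davis_hip_joint_centre <- function(leg_length, inter_asis,
                                   asis_trochanter_offset = NULL,
                                   marker_radius = 0,
                                   side = c("right", "left")) {
  side <- match.arg(side)
  if (!is.finite(leg_length) || leg_length <= 0)
    stop("leg_length must be > 0")
  if (!is.finite(inter_asis) || inter_asis <= 0)
    stop("inter_asis must be > 0")
  if (is.null(asis_trochanter_offset))
    asis_trochanter_offset <- 0.1288 * leg_length - 48.56
  if (!is.finite(asis_trochanter_offset) || asis_trochanter_offset <= 0)
    stop("asis_trochanter_offset must be > 0")
  if (!is.finite(marker_radius) || marker_radius < 0)
    stop("marker_radius must be >= 0")
  theta <- 28.4 * pi / 180
  beta <- 18 * pi / 180
  C <- 0.115 * leg_length - 15.3
  dr <- asis_trochanter_offset + marker_radius
  x <- C * cos(theta) * sin(beta) - dr * cos(beta)
  y <- -C * cos(theta) * cos(beta) - dr * sin(beta)
  z <- (inter_asis / 2 - C * sin(theta)) * if (side == "right") 1 else -1
  structure(list(position = c(x, y, z), side = side), class = "hjc")
}

## --- ISB frame recipes -----------------------------------------------------

#' Single-frame ISB segment frames
#'
#' Frame recipes (all landmarks in lab coordinates, mm):
#' \itemize{
#' \item pelvis: origin mid-ASIS; Z along the inter-ASIS line to the right;
#'   X in the plane of the ASISs and the PSIS midpoint, anterior; Y = Z x X.
#' \item femur: origin at the hip joint centre; Y from the epicondyle
#'   midpoint to the HJC; X perpendicular to the plane of HJC and both
#'   epicondyles, anterior; Z = X x Y.
#' \item shank: origin at the malleolar midpoint; Y from that midpoint
#'   towards the tibial condyle midpoint; X perpendicular to the plane
#'   spanned by Y and the malleolar axis, anterior; Z = X x Y.
#' }
#' @param rasis,lasis,rpsis,lpsis,hjc_lab,lep,mep,lcon,mcon,lmal,mmal
#'   3-vectors (lab, mm).
#' @return A [pose()]: anatomical frame in the lab.
#' @export
isb_pelvis_frame <- function(rasis, lasis, rpsis, lpsis) {
  o <- (rasis + lasis) / 2
  z <- unitv(rasis - lasis, "pelvis inter-ASIS axis")
  v <- o - (rpsis + lpsis) / 2
  x <- unitv(v - sum(v * z) * z, "pelvis anteroposterior axis")
  frame_from_axes(x, cross3(z, x), z, o)
}

#' @rdname isb_pelvis_frame
#' @export
isb_femur_frame <- function(hjc_lab, lep, mep) {
  mid <- (lep + mep) / 2
  y <- unitv(hjc_lab - mid, "femur longitudinal axis")
  x <- unitv(cross3(y, lep - mep), "femur anteroposterior axis")
  frame_from_axes(x, y, cross3(x, y), hjc_lab)
}

#' @rdname isb_pelvis_frame
#' @export
isb_shank_frame <- function(lcon, mcon, lmal, mmal) {
  o <- (lmal + mmal) / 2
  y <- unitv((lcon + mcon) / 2 - o, "shank longitudinal axis")
  x <- unitv(cross3(y, lmal - mmal), "shank anteroposterior axis")
  frame_from_axes(x, y, cross3(x, y), o)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

.isb_landmarks <- list(
  pelvis = c("RASIS", "LASIS", "RPSIS", "LPSIS"),
  femur = c("RLEPI", "RMEPI"),
  shank = c("RLCON", "RMCON", "RLMAL", "RMMAL"))

#' Build ISB anatomical frame time series
#'
#' Pelvis, femur and shank frames from landmark trajectories; the foot
#' anatomical frame is the shank anatomical frame captured in the neutral
#' static position and rigidly attached to the foot technical (cluster)
#' frame thereafter, so ankle angles are zero by construction in the
#' neutral stance.
#'
#' @param landmarks a [marker_trajectory_set()] of (virtual) landmark
#'   trajectories in the lab; names per `.isb_landmarks`.
#' @param hjc a [davis_hip_joint_centre()] result (pelvis-frame position).
#' @param foot_tech optional `pose_series` of the foot cluster technical
#'   frame (same frames as `landmarks`).
#' @param foot_offset optional [pose()]: foot anatomical frame expressed in
#'   the foot technical frame, from the neutral static trial (see
#'   [foot_neutral_offset()]).
#' @return A `segment_frame_set`: named list of `pose_series` for
#'   `pelvis`, `femur`, `shank` (and `foot` when the cluster inputs are
#'   given), plus `hjc_lab` (n x 3).
#' @export
build_isb_frames <- function(landmarks, hjc, foot_tech = NULL,
                             foot_offset = NULL) {
  stopifnot(inherits(landmarks, "mts"), inherits(hjc, "hjc"))
  need <- unique(unlist(.isb_landmarks))
  for (seg in names(.isb_landmarks)) {
    miss <- setdiff(.isb_landmarks[[seg]], landmarks$labels)
    if (length(miss))
      stop("missing landmark(s) for segment '", seg, "': ",
           paste(miss, collapse = ", "))
  }
  nf <- landmarks$n_frames
  segs <- c("pelvis", "femur", "shank")
  out <- lapply(segs, function(s)
    list(R = array(NA_real_, c(3, 3, nf)), t = matrix(NA_real_, 3, nf),
         valid = rep(FALSE, nf)))
  names(out) <- segs
  hjc_lab <- matrix(NA_real_, nf, 3)
  g <- function(l, f) landmarks$pos[[l]][f, ]
  vall <- function(labs, f) all(vapply(labs, function(l)
    landmarks$valid[[l]][f], logical(1)))
  for (f in seq_len(nf)) {
    if (!vall(need, f)) next
    pel <- isb_pelvis_frame(g("RASIS", f), g("LASIS", f),
                            g("RPSIS", f), g("LPSIS", f))
    hl <- pose_apply(pel, hjc$position)
    fem <- isb_femur_frame(hl, g("RLEPI", f), g("RMEPI", f))
    shk <- isb_shank_frame(g("RLCON", f), g("RMCON", f),
                           g("RLMAL", f), g("RMMAL", f))
    hjc_lab[f, ] <- hl
    for (s in segs) {
      p <- switch(s, pelvis = pel, femur = fem, shank = shk)
      out[[s]]$R[, , f] <- p$R; out[[s]]$t[, f] <- p$t
      out[[s]]$valid[f] <- TRUE
    }
  }
  out <- lapply(out, function(o) structure(o, class = "pose_series"))
  if (!is.null(foot_tech)) {
    if (is.null(foot_offset))
      stop("foot_tech given without foot_offset (neutral calibration)")
    foot <- list(R = array(NA_real_, c(3, 3, nf)),
                 t = matrix(NA_real_, 3, nf), valid = rep(FALSE, nf))
    for (f in which(foot_tech$valid)) {
      p <- pose_compose(pose_at(foot_tech, f), foot_offset)
      foot$R[, , f] <- p$R; foot$t[, f] <- p$t; foot$valid[f] <- TRUE
    }
    out$foot <- structure(foot, class = "pose_series")
  }
  out$hjc_lab <- hjc_lab
  structure(out, class = "segment_frame_set")
}

#' Neutral-position foot frame offset
#'
#' During the neutral static trial the foot anatomical frame is defined to
#' coincide with the shank anatomical frame; this returns that frame
#' expressed in the foot technical (cluster) frame, to be reattached
#' rigidly in dynamic trials.
#'
#' @param shank_anat [pose()] of the shank anatomical frame (static, lab).
#' @param foot_tech [pose()] of the foot technical frame (static, lab).
#' @return [pose()]: anatomical-in-technical offset.
#' @export
foot_neutral_offset <- function(shank_anat, foot_tech) {
  pose_compose(pose_invert(foot_tech), shank_anat)
}

## --- Helen Hayes / Davis conventional model --------------------------------

#' Chord joint-centre construction
#'
#' The joint centre lies in the plane of the proximal centre, the lateral
#' joint marker and the wand marker, at `offset` from the lateral marker,
#' with the centre-to-marker segment perpendicular to the centre-to-
#' proximal segment (the conventional-model "chord" function).
#'
#' @param prox proximal joint centre (lab, mm).
#' @param lateral lateral joint marker (lab, mm).
#' @param wand wand marker defining the segment frontal plane (lab, mm).
#' @param offset half joint width plus marker radius (mm).
#' @return 3-vector joint centre (lab, mm).
#' @export
chord_joint_centre <- function(prox, lateral, wand, offset) {
  e <- prox - lateral
  L <- vnorm(e)
  if (offset >= L)
    stop("chord offset (", offset, " mm) not smaller than the ",
         "marker-to-proximal distance (", round(L, 1), " mm)")
  eh <- e / L
  n <- unitv(cross3(wand - lateral, e), "wand plane normal")
  u <- cross3(n, eh)
  cphi <- offset / L
  sphi <- sqrt(1 - cphi^2)
  lateral + offset * (cphi * eh + sphi * u)
}

#' Build conventional-model (Helen Hayes/Davis) frame time series
#'
#' Pelvis from the ASIS markers and sacrum; hip joint centre by the Davis
#' regression in the pelvis frame; knee and ankle centres by the chord
#' construction with the wand markers defining the thigh and shank frontal
#' planes; foot direction from the heel and forefoot markers.
#'
#' @param markers a [marker_trajectory_set()] carrying the conventional
#'   marker complement.
#' @param hjc a [davis_hip_joint_centre()] result.
#' @param config a [marker_set_config()] with `model = "hh"` (role-to-label
#'   map and knee/ankle widths).
#' @return A `segment_frame_set` (pelvis, femur, shank, foot, `hjc_lab`).
#' @export
build_hh_frames <- function(markers, hjc, config) {
  stopifnot(inherits(markers, "mts"), inherits(hjc, "hjc"),
            inherits(config, "marker_set_config"))
  lab <- config$hh_labels
  roles <- c("RASIS", "LASIS", "SACR", "RTHI", "RKNE", "RTIB", "RANK",
             "RHEE", "RTOE")
  for (r in roles) {
    if (!lab[[r]] %in% markers$labels)
      stop("missing conventional-model marker '", r, "' (label '",
           lab[[r]], "')",
           if (r == "RTHI") " -- thigh wand" else
             if (r == "RTIB") " -- shank wand" else "")
  }
  a <- config$anthropometrics
  koff <- a$knee_width / 2 + a$marker_radius
  aoff <- a$ankle_width / 2 + a$marker_radius
  nf <- markers$n_frames
  segs <- c("pelvis", "femur", "shank", "foot")
  out <- lapply(segs, function(s)
    list(R = array(NA_real_, c(3, 3, nf)), t = matrix(NA_real_, 3, nf),
         valid = rep(FALSE, nf)))
  names(out) <- segs
  hjc_lab <- matrix(NA_real_, nf, 3)
  g <- function(r, f) markers$pos[[lab[[r]]]][f, ]
  for (f in seq_len(nf)) {
    ok <- all(vapply(roles, function(r) markers$valid[[lab[[r]]]][f],
                     logical(1)))
    if (!ok) next
    rasis <- g("RASIS", f); lasis <- g("LASIS", f); sacr <- g("SACR", f)
    o <- (rasis + lasis) / 2
    z <- unitv(rasis - lasis, "pelvis inter-ASIS axis")
    v <- o - sacr
    x <- unitv(v - sum(v * z) * z, "pelvis anteroposterior axis")
    pel <- frame_from_axes(x, cross3(z, x), z, o)
    hl <- pose_apply(pel, hjc$position)
    kjc <- chord_joint_centre(hl, g("RKNE", f), g("RTHI", f), koff)
    yf <- unitv(hl - kjc, "thigh longitudinal axis")
    zr <- g("RKNE", f) - kjc
    zf <- unitv(zr - sum(zr * yf) * yf, "thigh mediolateral axis")
    fem <- frame_from_axes(cross3(yf, zf), yf, zf, hl)
    ajc <- chord_joint_centre(kjc, g("RANK", f), g("RTIB", f), aoff)
    ys <- unitv(kjc - ajc, "shank longitudinal axis")
    zr <- g("RANK", f) - ajc
    zs <- unitv(zr - sum(zr * ys) * ys, "shank mediolateral axis")
    shk <- frame_from_axes(cross3(ys, zs), ys, zs, ajc)
    xt <- unitv(g("RTOE", f) - g("RHEE", f), "foot longitudinal axis")
    zt <- unitv(cross3(xt, ys), "foot mediolateral axis")
    fot <- frame_from_axes(xt, cross3(zt, xt), zt, ajc)
    hjc_lab[f, ] <- hl
    for (s in segs) {
      p <- switch(s, pelvis = pel, femur = fem, shank = shk, foot = fot)
      out[[s]]$R[, , f] <- p$R; out[[s]]$t[, f] <- p$t
      out[[s]]$valid[f] <- TRUE
    }
  }
  out <- lapply(out, function(o) structure(o, class = "pose_series"))
  out$hjc_lab <- hjc_lab
  structure(out, class = "segment_frame_set")
}
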