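#' Rigid-body pose estimation, pointer calibration and virtual markers
#'
#' Cluster-based segment tracking: each body segment carries a rigid cluster
#' of >= 3 noncollinear technical markers.  The pose of the cluster in the
#' laboratory is estimated per frame by least-squares orthogonal Procrustes;
#' anatomical landmarks registered once with a tracked pointer during a
#' static trial are then reconstructed dynamically as virtual markers.
#'
#' @name rigid_body
NULL

#' Least-squares rigid transform between two point sets
#'
#' SVD-based orthogonal Procrustes solution (Soederkvist-Wedin style) for the
#' rotation and translation mapping `reference` onto `observed`, minimising
#' the (weighted) sum of squared distances, with a reflection guard.
#'
#' @param reference n x 3 matrix of points in the reference (local) frame.
#' @param observed n x 3 matrix of the same points observed in the parent
#'   (lab) frame.
#' @param weights optional nonnegative length-n weights.
#' @param tol singular-value tolerance for collinearity detection, relative
#'   to the largest singular value of the centred reference spread.
#' @return List with `pose` (see [pose()]) and `rms` (residual root mean
#'   square distance, mm).
#' @export
fit_rigid_transform <- function(reference, observed, weights = NULL,
                                tol = 1e-8) {
  reference <- as.matrix(reference); observed <- as.matrix(observed)
  n <- nrow(reference)
  if (n < 3L) stop("at least 3 points are required to fit a rigid transform")
  if (!all(dim(reference) == dim(observed)))
    stop("reference and observed point sets differ in shape")
  if (any(!is.finite(reference)) || any(!is.finite(observed)))
    stop("non-finite coordinates in rigid transform fit")
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights < 0) || sum(weights) <= 0)
    stop("weights must be nonnegative with positive sum")
  w <- weights / sum(weights)

  cr <- colSums(reference * w)
  co <- colSums(observed * w)
  A <- sweep(reference, 2, cr)
  B <- sweep(observed, 2, co)
  # collinearity check on the reference spread
  sv_ref <- svd(A * sqrt(w), nu = 0, nv = 0)$d
  if (sv_ref[2] <= tol * max(sv_ref[1], .Machine$double.eps))
    stop("reference points are (near-)collinear; cluster geometry degenerate")

  H <- t(A * w) %*% B
  sv <- svd(H)
  D <- diag(c(1, 1, sign(det(sv$v %*% t(sv$u)))))
  R <- sv$v %*% D %*% t(sv$u)
  t_ <- co - as.numeric(R %*% cr)
  p <- pose(R, t_, check = FALSE)
  resid <- observed - pose_apply(p, reference)
  rms <- sqrt(sum(w * rowSums(resid^2)))
  list(pose = p, rms = rms)
}

#' Fit a pose time series for one marker cluster
#'
#' Runs [fit_rigid_transform()] frame by frame, mapping a fixed reference
#' geometry (usually the static-trial mean marker positions) onto the
#' observed marker positions.  Frames where any cluster marker is invalid
#' are flagged invalid, never fabricated.
#'
#' @param trajectories a [marker_trajectory_set()].
#' @param labels cluster marker labels (>= 3).
#' @param reference n x 3 reference geometry with rows in `labels` order;
#'   `NULL` takes the mean of valid frames of `trajectories` itself.
#' @return A `pose_series`: list with `R` (3x3xN), `t` (3xN), `valid`
#'   (logical N), `rms` (numeric N).
#' @export
fit_pose_series <- function(trajectories, labels, reference = NULL) {
  stopifnot(inherits(trajectories, "mts"))
  missing_lab <- setdiff(labels, trajectories$labels)
  if (length(missing_lab))
    stop("cluster markers absent from trajectories: ",
         paste(missing_lab, collapse = ", "))
  if (is.null(reference)) reference <- cluster_reference(trajectories, labels)
  nf <- trajectories$n_frames
  R <- array(NA_real_, c(3, 3, nf)); tr <- matrix(NA_real_, 3, nf)
  valid <- rep(FALSE, nf); rms <- rep(NA_real_, nf)
  vmat <- sapply(labels, function(l) trajectories$valid[[l]])
  if (nf == 1L) vmat <- matrix(vmat, nrow = 1L)
  for (f in seq_len(nf)) {
    if (!all(vmat[f, ])) next
    obs <- t(vapply(labels, function(l) trajectories$pos[[l]][f, ],
                    numeric(3)))
    fit <- fit_rigid_transform(reference, obs)
    R[, , f] <- fit$pose$R; tr[, f] <- fit$pose$t
    valid[f] <- TRUE; rms[f] <- fit$rms
  }
  structure(list(R = R, t = tr, valid = valid, rms = rms, labels = labels),
            class = "pose_series")
}

pose_at <- function(ps, frame) {
  if (!ps$valid[frame]) stop("pose invalid at frame ", frame)
  pose(ps$R[, , frame], ps$t[, frame], check = FALSE)
}

#' Mean cluster geometry from a static trial
#'
#' @param trajectories a [marker_trajectory_set()].
#' @param labels marker labels.
#' @return n x 3 matrix of mean positions over frames valid for all labels.
#' @export
cluster_reference <- function(trajectories, labels) {
  vmat <- sapply(labels, function(l) trajectories$valid[[l]])
  if (trajectories$n_frames == 1L) vmat <- matrix(vmat, nrow = 1L)
  ok <- rowSums(!vmat) == 0
  if (!any(ok)) stop("no frame with all cluster markers valid")
  t(vapply(labels, function(l) colMeans(trajectories$pos[[l]][ok, , drop = FALSE]),
           numeric(3)))
}

#' Pivot calibration of a tracked pointer tip
#'
#' The pointer is pivoted about its (stationary) tip; each frame gives pose
#' (R_i, d_i) of the pointer technical frame.  The constant tip offset `t_p`
#' in the pointer frame and the fixed pivot point `p` in the lab satisfy
#' `R_i t_p + d_i = p`, solved jointly in least squares.
#'
#' @param pointer_poses a `pose_series` (valid frames are used).
#' @param min_poses minimum number of valid poses (default 10).
#' @param diversity_tol smallest-singular-value threshold of the stacked
#'   system, relative to its largest; below it the rotation set is too
#'   uniform to observe the offset.
#' @return A `pointer_model`: list with `tip_offset` (3-vector, pointer
#'   frame, mm), `pivot_point` (lab, mm), `rms` (mm), `n_poses`.
#' @export
pivot_calibrate <- function(pointer_poses, min_poses = 10,
                            diversity_tol = 1e-6) {
  idx <- which(pointer_poses$valid)
  m <- length(idx)
  if (m < min_poses)
    stop("pivot calibration needs >= ", min_poses, " valid poses, got ", m)
  A <- matrix(0, 3 * m, 6); b <- numeric(3 * m)
  for (q in seq_len(m)) {
    f <- idx[q]; rows <- (3 * q - 2):(3 * q)
    A[rows, 1:3] <- pointer_poses$R[, , f]
    A[rows, 4:6] <- -diag(3)
    b[rows] <- -pointer_poses$t[, f]
  }
  sv <- svd(A)
  if (sv$d[6] <= diversity_tol * sv$d[1])
    stop("insufficient rotational diversity for pivot calibration ",
         "(rank-deficient system; pointer must be pivoted, not translated)")
  x <- sv$v %*% (crossprod(sv$u, b) / sv$d)
  resid <- A %*% x - b
  rms <- sqrt(mean(rowSums(matrix(resid^2, ncol = 3, byrow = TRUE))))
  structure(list(tip_offset = as.numeric(x[1:3]),
                 pivot_point = as.numeric(x[4:6]),
                 rms = rms, n_poses = m),
            class = "pointer_model")
}

#' Pointer tip position in the lab frame
#' @param pointer a `pointer_model`.
#' @param pointer_pose `pose` of the pointer technical frame in the lab.
#' @return 3-vector, lab frame (mm).
#' @export
pointer_tip <- function(pointer, pointer_pose) {
  pose_apply(pointer_pose, pointer$tip_offset)
}

#' Register an anatomical landmark in a cluster technical frame
#'
#' Expresses the pointer tip (touching the landmark during a static trial)
#' in the technical frame of the segment's marker cluster:
#' `v_local = R_c' (tip_lab - t_c)`.  With pose series inputs the result is
#' averaged over all frames where both poses are valid.
#'
#' @param pointer a `pointer_model` from [pivot_calibrate()].
#' @param pointer_pose `pose` or `pose_series` of the pointer.
#' @param cluster_pose `pose` or `pose_series` of the cluster (same frames).
#' @param frames optional frame subset for the averaging window (default:
#'   all jointly valid frames).
#' @return 3-vector in the cluster technical frame (mm) with attribute
#'   `n_frames` (averaging window actually used).
#' @export
register_landmark <- function(pointer, pointer_pose, cluster_pose,
                              frames = NULL) {
  one <- function(pp, cp) as.numeric(t(cp$R) %*% (pointer_tip(pointer, pp) - cp$t))
  if (inherits(pointer_pose, "pose") && inherits(cluster_pose, "pose")) {
    out <- one(pointer_pose, cluster_pose)
    attr(out, "n_frames") <- 1L
    return(out)
  }
  stopifnot(inherits(pointer_pose, "pose_series"),
            inherits(cluster_pose, "pose_series"))
  ok <- which(pointer_pose$valid & cluster_pose$valid)
  if (!is.null(frames)) ok <- intersect(ok, frames)
  if (!length(ok))
    stop("no frame with both pointer and cluster pose valid; ",
         "cannot register landmark")
  acc <- rowMeans(vapply(ok, function(f)
    one(pose_at(pointer_pose, f), pose_at(cluster_pose, f)), numeric(3)))
  out <- as.numeric(acc)
  attr(out, "n_frames") <- length(ok)
  out
}

#' Reconstruct a virtual marker in the lab frame
#'
#' `lab = R %*% local + t` using the cluster's current pose.  With a
#' `pose_series` the full trajectory is returned; frames with an invalid
#' cluster pose stay `NA` and are marked invalid.
#'
#' @param local_vector 3-vector in the cluster technical frame (mm).
#' @param cluster_pose `pose` or `pose_series`.
#' @return 3-vector, or list(`pos` N x 3, `valid` logical N).
#' @export
reconstruct_virtual_marker <- function(local_vector, cluster_pose) {
  if (inherits(cluster_pose, "pose"))
    return(pose_apply(cluster_pose, local_vector))
  stopifnot(inherits(cluster_pose, "pose_series"))
  nf <- length(cluster_pose$valid)
  pos <- matrix(NA_real_, nf, 3)
  for (f in which(cluster_pose$valid))
    pos[f, ] <- as.numeric(cluster_pose$R[, , f] %*% local_vector +
                             cluster_pose$t[, f])
  list(pos = pos, valid = cluster_pose$valid)
}
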