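#' Rigid-body poses and Cardan angle decomposition
#'
#' A pose is the orientation and position of a (technical or anatomical)
#' coordinate frame in a parent frame: `x_parent = R %*% x_local + t`.
#' Columns of `R` are the local axes expressed in the parent frame.
#'
#' @name pose
NULL

#' Construct a pose
#'
#' @param R 3x3 rotation matrix (orthonormal, det +1).
#' @param t length-3 translation vector (mm).
#' @param check validate the rotation invariants (default TRUE).
#' @return An object of class `pose` with elements `R` and `t`.
#' @export
pose <- function(R = diag(3), t = c(0, 0, 0), check = TRUE) {
  R <- unname(as.matrix(R))
  t <- unname(as.numeric(t))
  if (!all(dim(R) == c(3L, 3L))) stop("pose rotation must be 3x3")
  if (length(t) != 3L) stop("pose translation must be length 3")
  if (check) assert_rotation(R)
  structure(list(R = R, t = t), class = "pose")
}

#' @export
print.pose <- function(x, ...) {
  cat("pose: translation [mm] =", format(x$t, digits = 6), "\n")
  print(x$R)
  invisible(x)
}

assert_rotation <- function(R, tol = 1e-9) {
  if (any(!is.finite(R))) stop("rotation contains non-finite values")
  if (max(abs(crossprod(R) - diag(3))) > tol)
    stop("rotation is not orthonormal (||R'R - I|| > ", tol, ")")
  if (abs(det(R) - 1) > tol)
    stop("rotation has det != +1 (reflection or degenerate)")
  invisible(R)
}

is_valid_rotation <- function(R, tol = 1e-9) {
  all(is.finite(R)) && max(abs(crossprod(R) - diag(3))) <= tol &&
    abs(det(R) - 1) <= tol
}

#' Apply a pose to local points
#'
#' @param p `pose` object.
#' @param x 3-vector or n x 3 matrix of points in the local frame.
#' @return Points in the parent frame, same shape as `x`.
#' @export
pose_apply <- function(p, x) {
  if (is.matrix(x)) {
    sweep(x %*% t(p$R), 2, -p$t)
  } else {
    as.numeric(p$R %*% x + p$t)
  }
}

#' Invert a pose
#' @param p `pose` object.
#' @return The inverse pose (parent expressed in the local frame).
#' @export
pose_invert <- function(p) {
  pose(t(p$R), -as.numeric(t(p$R) %*% p$t), check = FALSE)
}

#' Compose two poses
#'
#' `pose_compose(a, b)` is the pose of frame c in frame's a parent when `b`
#' is the pose of c in the frame described by `a`.
#' @param a,b `pose` objects.
#' @return Composed `pose`.
#' @export
pose_compose <- function(a, b) {
  pose(a$R %*% b$R, as.numeric(a$R %*% b$t + a$t), check = FALSE)
}

## --- elementary rotations ------------------------------------------------

#' Elementary rotation matrices
#'
#' Right-handed rotations about the x, y or z axis.
#' @param theta angle in radians.
#' @return 3x3 rotation matrix.
#' @export
rot_x <- function(theta) {
  c <- cos(theta); s <- sin(theta)
  matrix(c(1, 0, 0, 0, c, s, 0, -s, c), 3, 3)
}

#' @rdname rot_x
#' @export
rot_y <- function(theta) {
  c <- cos(theta); s <- sin(theta)
  matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3, 3)
}

#' @rdname rot_x
#' @export
rot_z <- function(theta) {
  c <- cos(theta); s <- sin(theta)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
}

rot_axis <- function(axis, theta) {
  switch(axis, x = rot_x(theta), y = rot_y(theta), z = rot_z(theta),
         stop("unknown axis: ", axis))
}

.axis_index <- c(x = 1L, y = 2L, z = 3L)

.sequence_axes <- function(sequence) {
  ax <- strsplit(tolower(sequence), "")[[1]]
  if (length(ax) != 3L || anyDuplicated(ax) || !all(ax %in% c("x", "y", "z")))
    stop("Cardan sequence must be three distinct axes, e.g. \"zxy\"")
  ax
}

#' Compose a rotation from Cardan angles
#'
#' Intrinsic rotations applied in the order given by `sequence`:
#' `R = R_i(angles[1]) %*% R_j(angles[2]) %*% R_k(angles[3])`.
#'
#' @param angles length-3 numeric, degrees.
#' @param sequence three-letter axis order, default `"zxy"` (flexion about the
#'   proximal mediolateral axis, then ab/adduction, then axial rotation --
#'   the joint-coordinate-system-equivalent ordering).
#' @return 3x3 rotation matrix.
#' @export
cardan_compose <- function(angles, sequence = "zxy") {
  ax <- .sequence_axes(sequence)
  th <- angles * pi / 180
  rot_axis(ax[1], th[1]) %*% rot_axis(ax[2], th[2]) %*% rot_axis(ax[3], th[3])
}

#' Decompose a rotation into Cardan angles
#'
#' Inverse of [cardan_compose()]: returns the three angles (degrees) whose
#' intrinsic recomposition in `sequence` reproduces `R`.  The middle angle is
#' kept in (-90, 90) degrees.  Near gimbal lock (|middle| > `gimbal_limit`)
#' the first and third rotations are no longer separable; the third angle is
#' set to zero by convention and the result carries attribute
#' `gimbal = TRUE`.
#'
#' @param R 3x3 rotation matrix.
#' @param sequence three-letter axis order, default `"zxy"`.
#' @param gimbal_limit degrees; middle angles beyond this flag gimbal
#'   proximity (default 89.9).
#' @return Numeric length 3 (degrees), attribute `gimbal` logical.
#' @export
cardan_decompose <- function(R, sequence = "zxy", gimbal_limit = 89.9) {
  assert_rotation(R)
  ax <- .sequence_axes(sequence)
  i <- .axis_index[ax[1]]; j <- .axis_index[ax[2]]; k <- .axis_index[ax[3]]
  # sign of the axis permutation: +1 for cyclic (xyz, yzx, zxy)
  s <- if (paste(ax, collapse = "") %in% c("xyz", "yzx", "zxy")) 1 else -1
  sb <- max(-1, min(1, s * R[i, k]))
  beta <- asin(sb)
  gimbal <- abs(beta) * 180 / pi > gimbal_limit
  if (abs(abs(sb) - 1) < 1e-12) {
    # exact lock: alpha and gamma degenerate; fix gamma = 0
    gamma <- 0
    alpha <- atan2(s * R[j, i] * sign(sb), R[j, j])
  } else {
    alpha <- atan2(-s * R[j, k], R[k, k])
    gamma <- atan2(-s * R[i, j], R[i, i])
  }
  out <- c(alpha, beta, gamma) * 180 / pi
  attr(out, "gimbal") <- gimbal
  out
}

## --- random rotations (testing / synthetic use) --------------------------

#' Uniform random rotation matrices
#'
#' Draws rotations uniformly (Haar measure) via QR of a Gaussian matrix.
#' @param n number of rotations.
#' @return 3x3xN array.
#' @export
random_rotations <- function(n) {
  out <- array(NA_real_, c(3, 3, n))
  for (m in seq_len(n)) {
    qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
    Q <- qr.Q(qr_)
    d <- sign(diag(qr.R(qr_)))
    Q <- Q %*% diag(d)
    if (det(Q) < 0) Q[, 1] <- -Q[, 1]
    out[, , m] <- Q
  }
  out
}
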