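#' Trajectory filtering, gait events and time normalisation
#'
#' Marker trajectories are smoothed with a zero-lag low-pass Butterworth
#' filter before pose fitting; gait cycles (ipsilateral foot strike to
#' foot strike) are detected from the heel trajectory or supplied
#' explicitly; each rotation curve is then resampled to 101 points per
#' cycle (0-100 % of the gait cycle).
#'
#' @name cycle_processing
NULL

#' Zero-lag low-pass Butterworth filter
#'
#' Dual-pass (forward-backward) Butterworth with the cutoff corrected so
#' that the effective (two-pass) response is -3 dB at `cutoff`.  The
#' correction is applied in the prewarped analog domain, making the gain at
#' `cutoff` exactly 1/sqrt(2).  The series mean is removed before
#' filtering and restored afterwards, and the series is extended by
#' reflection to keep end transients outside the data, so the DC gain is
#' exactly 1.  `mode = "effective"` (default) realises a 4th-order
#' effective filter as two 2nd-order passes; `mode = "per_pass"` designs
#' `order` directly in each pass (effective order `2 * order`).
#'
#' @param series numeric vector (no NAs).
#' @param rate sampling frequency, Hz.
#' @param cutoff -3 dB frequency, Hz (default 6).
#' @param order filter order (default 4; must be even for
#'   `mode = "effective"`).
#' @param mode `"effective"` or `"per_pass"`.
#' @return Filtered series, same length.
#' @export
butterworth_lowpass <- function(series, rate, cutoff = 6, order = 4,
                                mode = c("effective", "per_pass")) {
  mode <- match.arg(mode)
  if (any(!is.finite(series)))
    stop("series contains non-finite values; resolve gaps before filtering")
  if (cutoff >= rate / 2)
    stop("cutoff (", cutoff, " Hz) must be below the Nyquist frequency (",
         rate / 2, " Hz)")
  per_pass <- if (mode == "effective") {
    if (order %% 2L != 0L)
      stop("effective mode needs an even order (got ", order, ")")
    order %/% 2L
  } else order
  n <- length(series)
  if (n < 3L * order)
    stop("series too short for filtering (need >= ", 3L * order,
         " samples, got ", n, ")")
  # prewarped cutoff correction: two passes of order p attenuate to
  # (1 + w^2p)^-1; -3 dB at the nominal cutoff requires the per-pass analog
  # cutoff to be larger by (2^(1/2) - 1)^(-1/(2p)).
  corr <- (sqrt(2) - 1)^(-1 / (2 * per_pass))
  w_warp <- tan(pi * cutoff / rate) * corr
  Wc <- atan(w_warp) * 2 / pi           # normalised (Nyquist = 1)
  if (Wc >= 1) stop("corrected cutoff reaches Nyquist; increase rate")
  bf <- signal::butter(per_pass, Wc, type = "low")
  mu <- mean(series)
  x <- series - mu
  pad <- min(n - 1L, as.integer(ceiling(6 * rate / cutoff)))
  xx <- c(2 * x[1] - x[(pad + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - pad)])
  y <- signal::filter(bf, xx)
  y <- rev(signal::filter(bf, rev(y)))
  y[(pad + 1L):(pad + n)] + mu
}

#' Filter all trajectories of a marker set
#'
#' Applies [butterworth_lowpass()] per coordinate.  Only markers without
#' gaps are filtered; trajectories containing invalid samples are left
#' untouched (gaps are never silently interpolated).
#'
#' @param trajectories a [marker_trajectory_set()].
#' @inheritParams butterworth_lowpass
#' @return A filtered [marker_trajectory_set()].
#' @export
filter_trajectories <- function(trajectories, cutoff = 6, order = 4,
                                mode = "effective") {
  x <- trajectories
  pos <- x$pos
  for (l in x$labels) {
    if (!all(x$valid[[l]])) next
    for (d in 1:3)
      pos[[l]][, d] <- butterworth_lowpass(pos[[l]][, d], x$rate, cutoff,
                                           order, mode)
  }
  marker_trajectory_set(pos, x$rate, x$valid)
}

#' Detect foot-strike events from heel kinematics
#'
#' Coordinate-based detection: foot strikes are local maxima of the heel
#' position along the progression axis measured relative to the pelvis
#' (the heel is most anterior of the pelvis at initial contact).  This is
#' a stand-in for manual event selection; user-supplied events always
#' override it downstream.
#'
#' @param heel n x 3 heel (or heel-marker) trajectory, lab, mm.
#' @param pelvis n x 3 pelvis origin trajectory (e.g. mid-ASIS or sacrum).
#' @param rate sampling frequency, Hz.
#' @param progression progression axis index (1-3) or `NULL` to estimate it
#'   from the dominant pelvis displacement.
#' @param min_stride minimum stride duration in seconds (default 0.4).
#' @return Integer vector of foot-strike frames (sorted).
#' @export
detect_foot_strikes <- function(heel, pelvis, rate, progression = NULL,
                                min_stride = 0.4) {
  heel <- as.matrix(heel); pelvis <- as.matrix(pelvis)
  if (is.null(progression)) {
    disp <- abs(pelvis[nrow(pelvis), ] - pelvis[1, ])
    if (max(disp) < 100)
      stop("no gait detected: pelvis displacement below 100 mm ",
           "(stationary markers?)")
    progression <- which.max(disp)
  }
  relx <- heel[, progression] - pelvis[, progression]
  n <- length(relx)
  gap <- max(3L, as.integer(round(min_stride * rate / 2)))
  peaks <- integer(0)
  for (f in 2:(n - 1L)) {
    lo <- max(1L, f - gap); hi <- min(n, f + gap)
    if (relx[f] >= max(relx[lo:hi]) && relx[f] > relx[lo] &&
        relx[f] > relx[hi])
      peaks <- c(peaks, f)
  }
  # collapse plateaus / near-duplicates
  if (length(peaks) > 1L)
    peaks <- peaks[c(TRUE, diff(peaks) > gap)]
  if (length(peaks) < 2L)
    stop("no periodic foot strikes found in the heel trajectory")
  amp <- diff(range(relx))
  if (amp < 50)
    stop("heel excursion too small (", round(amp, 1),
         " mm) for event detection")
  sort(peaks)
}

#' Time-normalise one cycle to 101 samples
#'
#' Linear interpolation of the curve onto 101 equally spaced points of
#' `[start, end]` (0 to 100 % of the gait cycle); endpoints are preserved
#' exactly.
#'
#' @param curve numeric vector over frames.
#' @param start,end cycle boundary frames (start < end), inclusive.
#' @param valid optional logical vector; invalid samples inside the window
#'   are an error (gaps must be resolved upstream).
#' @return Numeric vector of length 101.
#' @export
normalize_cycle <- function(curve, start, end, valid = NULL) {
  if (!(start >= 1 && end <= length(curve) && start < end))
    stop("invalid cycle window [", start, ", ", end, "]")
  idx <- start:end
  if (!is.null(valid) && any(!valid[idx]))
    stop("invalid samples inside the cycle window; resolve gaps upstream")
  seg <- curve[idx]
  if (any(!is.finite(seg)))
    stop("non-finite samples inside the cycle window")
  grid <- seq(start, end, length.out = 101L)
  out <- stats::approx(idx, seg, xout = grid)$y
  out[1] <- seg[1]; out[101] <- seg[length(seg)]
  out
}

#' Normalise all 12 rotations of one cycle
#'
#' @param curves a `joint_angle_curves` (see [compute_joint_angles()]).
#' @param start,end foot-strike frames delimiting the cycle.
#' @param trial_id,cycle_index optional identifiers stored as attributes.
#' @return A `gait_cycle`: 101 x 12 matrix (degrees), columns
#'   [rotation_labels()], attributes `events = c(start, end)`, `trial_id`,
#'   `cycle_index`.
#' @export
normalize_gait_cycle <- function(curves, start, end, trial_id = NA,
                                 cycle_index = NA) {
  stopifnot(inherits(curves, "joint_angle_curves"))
  m <- vapply(rotation_labels(), function(l)
    normalize_cycle(curves$angles[, l], start, end, curves$valid),
    numeric(101L))
  structure(m, class = c("gait_cycle", class(m)),
            events = c(start = start, end = end),
            trial_id = trial_id, cycle_index = cycle_index)
}
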