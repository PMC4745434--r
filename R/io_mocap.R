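#' Labelled 3-D marker trajectories
#'
#' The central raw-data container: one position time series per marker
#' label, a sampling rate, and a per-label validity mask for gaps.  All
#' coordinates are millimetres.
#'
#' @param pos named list of n x 3 numeric matrices (one per marker label),
#'   all with the same row count.
#' @param rate sampling frequency, Hz (> 0).
#' @param valid optional named list of logical vectors (length n) marking
#'   valid frames; default: frames with all-finite coordinates.
#' @return Object of class `mts` with elements `labels`, `pos`, `valid`,
#'   `rate`, `n_frames`.
#' @export
marker_trajectory_set <- function(pos, rate, valid = NULL) {
  if (!length(pos) || is.null(names(pos)) || any(!nzchar(names(pos))))
    stop("pos must be a non-empty named list of n x 3 matrices")
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stop("rate must be a positive number (Hz)")
  pos <- lapply(pos, function(m) {
    m <- as.matrix(m)
    if (ncol(m) != 3L) stop("each trajectory must have 3 columns (x, y, z)")
    storage.mode(m) <- "double"
    unname(m)
  })
  nf <- unique(vapply(pos, nrow, integer(1)))
  if (length(nf) != 1L)
    stop("all labelled series must have equal frame count")
  if (is.null(valid)) {
    valid <- lapply(pos, function(m) rowSums(!is.finite(m)) == 0)
  } else {
    if (!setequal(names(valid), names(pos)))
      stop("valid mask labels must match pos labels")
    valid <- lapply(names(pos), function(l) {
      v <- as.logical(valid[[l]])
      if (length(v) != nf) stop("valid mask length mismatch for ", l)
      v & rowSums(!is.finite(pos[[l]])) == 0
    })
    names(valid) <- names(pos)
  }
  for (l in names(pos))
    if (any(!is.finite(pos[[l]][valid[[l]], ])))
      stop("non-finite coordinates flagged valid for ", l)
  structure(list(labels = names(pos), pos = pos, valid = valid,
                 rate = rate, n_frames = nf),
            class = "mts")
}

#' @export
print.mts <- function(x, ...) {
  cat("marker trajectory set:", length(x$labels), "markers x", x$n_frames,
      "frames @", x$rate, "Hz\n")
  gaps <- sum(vapply(x$valid, function(v) sum(!v), integer(1)))
  cat("  labels:", paste(utils::head(x$labels, 8), collapse = ", "),
      if (length(x$labels) > 8) "...", "\n  invalid samples:", gaps, "\n")
  invisible(x)
}

#' Subset an mts by label
#' @param x `mts`; @param labels labels to keep.
#' @return `mts` with only those labels.
#' @export
mts_select <- function(x, labels) {
  miss <- setdiff(labels, x$labels)
  if (length(miss)) stop("labels absent: ", paste(miss, collapse = ", "))
  marker_trajectory_set(x$pos[labels], x$rate, x$valid[labels])
}

## --- CSV dialect ----------------------------------------------------------
## header: frame,<label>_x,<label>_y,<label>_z,...  blank cells are gaps.

#' Read marker trajectories from CSV
#'
#' Dialect: comma separated, dot decimal, header
#' `frame,<label>_x,<label>_y,<label>_z,...`; blank cells are gaps and are
#' marked invalid; the frame column must be strictly increasing.
#'
#' @param path file path.
#' @param rate sampling frequency in Hz (the dialect does not carry it).
#' @return A [marker_trajectory_set()].
#' @export
read_csv_trajectories <- function(path, rate) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!ncol(df) || names(df)[1] != "frame")
    stop("trajectory CSV must start with a 'frame' column: ", path)
  cn <- names(df)[-1]
  if (length(cn) %% 3L != 0L)
    stop("coordinate columns not a multiple of 3 in ", path)
  if (!length(cn)) stop("no marker columns in ", path)
  frames <- df[[1]]
  if (any(diff(frames) <= 0))
    stop("frame column not strictly increasing in ", path)
  base <- sub("_[xyz]$", "", cn)
  labels <- unique(base)
  pos <- list()
  for (l in labels) {
    want <- paste0(l, "_", c("x", "y", "z"))
    if (!all(want %in% cn))
      stop("incomplete x/y/z triplet for marker '", l, "' in ", path)
    pos[[l]] <- as.matrix(df[, want])
  }
  marker_trajectory_set(pos, rate)
}

#' Write marker trajectories to CSV
#'
#' Inverse of [read_csv_trajectories()]; invalid samples are written as
#' blank cells.
#'
#' @param trajectories a [marker_trajectory_set()].
#' @param path output file path.
#' @param digits significant digits (default 10).
#' @export
write_csv_trajectories <- function(trajectories, path, digits = 10) {
  x <- trajectories
  cols <- list(frame = seq_len(x$n_frames))
  for (l in x$labels) {
    m <- x$pos[[l]]
    m[!x$valid[[l]], ] <- NA_real_
    cols[[paste0(l, "_x")]] <- m[, 1]
    cols[[paste0(l, "_y")]] <- m[, 2]
    cols[[paste0(l, "_z")]] <- m[, 3]
  }
  df <- as.data.frame(cols, check.names = FALSE)
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(v) ifelse(is.na(v), "",
                                                formatC(v, digits = digits, format = "g")))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## --- angle-curve CSV -------------------------------------------------------

#' The 12 reported rotations, in conventional report order
#'
#' Pelvis (vs laboratory) tilt/obliquity/rotation, then hip, knee and ankle
#' triples of the right limb.
#' @return Character vector of length 12.
#' @export
rotation_labels <- function() {
  c("pelvis_tilt", "pelvis_obliquity", "pelvis_rotation",
    "hip_flex_ext", "hip_abd_add", "hip_int_ext",
    "knee_flex_ext", "knee_var_valg", "knee_int_ext",
    "ankle_dor_pla", "ankle_inv_ev", "ankle_abd_add")
}

#' Write joint-angle curves to CSV
#'
#' One row per sample, one column per rotation, header in the standard
#' 12-rotation order (plus a leading `sample` column).
#'
#' @param curves numeric matrix, samples x 12, columns named as
#'   [rotation_labels()] (a `gait_cycle` object qualifies).
#' @param path output file path.
#' @export
write_angle_curves <- function(curves, path) {
  curves <- as.matrix(curves)
  if (ncol(curves) != 12L || !identical(colnames(curves), rotation_labels()))
    stop("angle curves must have the 12 standard rotation columns in order")
  if (any(!is.finite(curves))) stop("angle curves contain non-finite values")
  df <- data.frame(sample = seq_len(nrow(curves)) - 1L, curves,
                   check.names = FALSE)
  ok <- tryCatch({
    utils::write.csv(format(df, digits = 15, trim = TRUE), path,
                     row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) stop("failed writing angle curves to ", path, ": ",
                              conditionMessage(e)))
  invisible(path)
}

#' Read joint-angle curves written by [write_angle_curves()]
#' @param path file path.
#' @return samples x 12 matrix with rotation-label column names.
#' @export
read_angle_curves <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!identical(names(df)[-1], rotation_labels()))
    stop("angle CSV does not carry the 12 standard rotation columns: ", path)
  as.matrix(df[, -1])
}

## --- gap filling -----------------------------------------------------------

#' Fill short marker gaps by cubic spline interpolation
#'
#' Explicit, never implicit: gaps at most `max_gap` frames long (and not at
#' the series edges) are interpolated per coordinate with a natural cubic
#' spline through the valid samples; longer or edge gaps stay invalid.
#'
#' @param trajectories a [marker_trajectory_set()].
#' @param max_gap longest run of invalid frames to fill (default 10).
#' @return A new [marker_trajectory_set()].
#' @export
fill_gaps <- function(trajectories, max_gap = 10) {
  x <- trajectories
  pos <- x$pos; valid <- x$valid
  for (l in x$labels) {
    v <- valid[[l]]
    if (all(v) || sum(v) < 4L) next
    r <- rle(v)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (g in which(!r$values)) {
      if (starts[g] == 1L || ends[g] == x$n_frames) next
      if (r$lengths[g] > max_gap) next
      idx <- starts[g]:ends[g]
      for (d in 1:3) {
        pos[[l]][idx, d] <- stats::spline(x = which(v), y = pos[[l]][v, d],
                                          xout = idx, method = "natural")$y
      }
      valid[[l]][idx] <- TRUE
    }
  }
  marker_trajectory_set(pos, x$rate, valid)
}

## --- marker-set configuration ----------------------------------------------

#' Marker-set / protocol configuration
#'
#' Describes one of the two supported protocols: `"isb6dof"` (four technical
#' clusters + pointer-calibrated virtual landmarks) or `"hh"` (skin and wand
#' markers, Helen Hayes/Davis conventional model).
#'
#' @param model `"isb6dof"` or `"hh"`.
#' @param clusters named list: segment -> >= 3 distinct technical marker
#'   labels (isb6dof).
#' @param landmarks named character vector: landmark label -> segment whose
#'   cluster carries it (isb6dof).
#' @param pointer_labels pointer body marker labels (isb6dof).
#' @param hh_labels named character vector mapping conventional-model roles
#'   (`RASIS`, `LASIS`, `SACR`, `RTHI`, `RKNE`, `RTIB`, `RANK`, `RHEE`,
#'   `RTOE`) to marker labels (hh).
#' @param anthropometrics named list: `leg_length`, `inter_asis`,
#'   `knee_width`, `ankle_width`, `marker_radius` (mm; all > 0 except
#'   `marker_radius` which may be 0).
#' @return Object of class `marker_set_config`.
#' @export
marker_set_config <- function(model = c("isb6dof", "hh"),
                              clusters = NULL, landmarks = NULL,
                              pointer_labels = NULL, hh_labels = NULL,
                              anthropometrics = list()) {
  model <- match.arg(model)
  req <- c("leg_length", "inter_asis", "marker_radius")
  miss <- setdiff(req, names(anthropometrics))
  if (length(miss))
    stop("missing anthropometrics: ", paste(miss, collapse = ", "))
  a <- anthropometrics
  pos_req <- setdiff(names(a), "marker_radius")
  bad <- pos_req[vapply(a[pos_req], function(v) !is.finite(v) || v <= 0,
                        logical(1))]
  if (length(bad) || !is.finite(a$marker_radius) || a$marker_radius < 0)
    stop("anthropometrics must be strictly positive (marker_radius >= 0)",
         if (length(bad)) paste0(": ", paste(bad, collapse = ", ")))
  if (model == "isb6dof") {
    if (is.null(clusters) || !length(clusters))
      stop("isb6dof configuration requires cluster definitions")
    for (seg in names(clusters)) {
      lab <- clusters[[seg]]
      if (length(unique(lab)) < 3L)
        stop("cluster '", seg, "' must list >= 3 distinct marker labels")
    }
    if (is.null(landmarks)) stop("isb6dof configuration requires landmarks")
    if (is.null(pointer_labels) || length(unique(pointer_labels)) < 3L)
      stop("pointer body needs >= 3 distinct marker labels")
  } else {
    if (is.null(hh_labels)) stop("hh configuration requires hh_labels")
    roles <- c("RASIS", "LASIS", "SACR", "RTHI", "RKNE", "RTIB", "RANK",
               "RHEE", "RTOE")
    miss <- setdiff(roles, names(hh_labels))
    if (length(miss))
      stop("hh_labels missing roles: ", paste(miss, collapse = ", "))
    if (!all(c("knee_width", "ankle_width") %in% names(a)))
      stop("hh model requires knee_width and ankle_width anthropometrics")
  }
  structure(list(model = model, clusters = clusters,
                 landmarks = landmarks, pointer_labels = pointer_labels,
                 hh_labels = hh_labels, anthropometrics = a),
            class = "marker_set_config")
}

#' Read / write marker-set configuration as YAML
#' @param path file path.
#' @return [marker_set_config()] (read) or `path` invisibly (write).
#' @export
read_marker_set_config <- function(path) {
  y <- yaml::read_yaml(path)
  marker_set_config(model = y$model, clusters = y$clusters,
                    landmarks = unlist(y$landmarks),
                    pointer_labels = y$pointer_labels,
                    hh_labels = unlist(y$hh_labels),
                    anthropometrics = y$anthropometrics)
}

#' @rdname read_marker_set_config
#' @param config a [marker_set_config()].
#' @export
write_marker_set_config <- function(config, path) {
  yaml::write_yaml(list(model = config$model, clusters = config$clusters,
                        landmarks = as.list(config$landmarks),
                        pointer_labels = config$pointer_labels,
                        hh_labels = as.list(config$hh_labels),
                        anthropometrics = config$anthropometrics), path)
  invisible(path)
}
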