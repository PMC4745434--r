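#' Repeatability and protocol-comparison statistics
#'
#' Ensemble means and SD bands over gait cycles, intertrial variability
#' (per-sample SD across one subject's trials), average intertrial
#' variability (AIT: SD curves averaged across the cycle, then across
#' subjects), averaged intraprotocol variability (AIP: per-sample SD
#' across subjects' mean curves, averaged across the cycle), mean absolute
#' variability between two protocols (MAV: mean |difference| over the
#' cycle per subject, then across subjects) and range of motion (ROM).
#' Sample standard deviations use the n-1 denominator throughout.
#'
#' @name variability_stats
NULL

.check_cycles <- function(cycles, min_n = 2L) {
  if (!is.list(cycles) || length(cycles) < min_n)
    stop("need at least ", min_n, " cycles")
  for (cy in cycles) {
    cy <- as.matrix(cy)
    if (!all(dim(cy) == c(101L, 12L)) ||
        !identical(colnames(cy), rotation_labels()))
      stop("every cycle must be a 101 x 12 matrix with the standard ",
           "rotation columns")
  }
  invisible(TRUE)
}

#' Per-sample ensemble mean and SD over cycles
#'
#' @param cycles list of >= 2 `gait_cycle` matrices (101 x 12).
#' @return List with `mean` and `sd` (101 x 12 matrices) and `n`.
#' @export
ensemble_mean_sd <- function(cycles) {
  .check_cycles(cycles)
  arr <- simplify2array(lapply(cycles, as.matrix))   # 101 x 12 x n
  mu <- apply(arr, c(1, 2), mean)
  sdv <- apply(arr, c(1, 2), stats::sd)
  dimnames(mu) <- dimnames(sdv) <- list(NULL, rotation_labels())
  list(mean = mu, sd = sdv, n = length(cycles))
}

#' Intertrial SD curves for one subject
#'
#' Per-sample standard deviation across the trials of a single subject
#' under one protocol.
#'
#' @param trials list of >= 2 `gait_cycle` matrices of one subject.
#' @param subject optional subject id; if the cycles carry a `subject`
#'   attribute, mixing subjects is an error.
#' @return 101 x 12 SD matrix (degrees).
#' @export
intertrial_sd_curve <- function(trials, subject = NULL) {
  .check_cycles(trials)
  subj <- unique(c(subject,
                   unlist(lapply(trials, attr, which = "subject"))))
  subj <- subj[!is.na(subj)]
  if (length(subj) > 1L)
    stop("intertrial variability is defined within one subject; got: ",
         paste(subj, collapse = ", "))
  ensemble_mean_sd(trials)$sd
}

#' Average intertrial variability (AIT)
#'
#' Each subject's intertrial SD curve is averaged across the 101 cycle
#' samples, then across subjects.
#'
#' @param sd_curves list (>= 1 per subject) of 101 x 12 SD matrices.
#' @return Named numeric vector, one AIT (degrees) per rotation.
#' @export
average_intertrial_variability <- function(sd_curves) {
  if (!is.list(sd_curves) || !length(sd_curves))
    stop("need at least one subject SD curve")
  per_subject <- vapply(sd_curves, function(s) colMeans(as.matrix(s)),
                        numeric(12L))
  out <- rowMeans(per_subject)
  names(out) <- rotation_labels()
  out
}

#' Averaged intraprotocol variability (AIP)
#'
#' Per-sample SD across the subjects' mean cycles, averaged across the
#' gait cycle: the subject-to-subject variability of a protocol.
#'
#' @param subject_means list of >= 2 mean `gait_cycle` matrices (one per
#'   subject).
#' @return Named numeric vector, one AIP (degrees) per rotation.
#' @export
averaged_intraprotocol_variability <- function(subject_means) {
  .check_cycles(subject_means, min_n = 2L)
  colMeans(ensemble_mean_sd(subject_means)$sd)
}

#' Mean absolute variability between two protocols (MAV)
#'
#' For each subject the paired curves of the two protocols are compared as
#' the mean absolute difference over the 101 cycle samples; the per-subject
#' values are then averaged.
#'
#' @param cycles_a,cycles_b named lists of `gait_cycle` matrices (typically
#'   per-subject mean cycles), paired by name.
#' @return Named numeric vector, one MAV (degrees) per rotation.
#' @export
mean_absolute_variability <- function(cycles_a, cycles_b) {
  if (is.null(names(cycles_a)) || is.null(names(cycles_b)))
    stop("protocol cycle lists must be named by subject for pairing")
  if (!setequal(names(cycles_a), names(cycles_b)))
    stop("unpaired subjects: ",
         paste(c(setdiff(names(cycles_a), names(cycles_b)),
                 setdiff(names(cycles_b), names(cycles_a))), collapse = ", "))
  .check_cycles(cycles_a, 1L); .check_cycles(cycles_b, 1L)
  per_subject <- vapply(names(cycles_a), function(s)
    colMeans(abs(as.matrix(cycles_a[[s]]) - as.matrix(cycles_b[[s]]))),
    numeric(12L))
  out <- rowMeans(per_subject)
  names(out) <- rotation_labels()
  out
}

#' Range of motion of an angle curve
#'
#' @param curve numeric vector (degrees) or a `gait_cycle` matrix (then one
#'   ROM per rotation).
#' @return max - min (degrees); named vector for matrices.
#' @export
range_of_motion <- function(curve) {
  if (is.matrix(curve)) {
    out <- apply(curve, 2, function(v) diff(range(v)))
    return(out)
  }
  if (any(!is.finite(curve))) stop("curve contains non-finite values")
  diff(range(curve))
}

#' Full variability report for a two-protocol study
#'
#' Assembles the per-rotation repeatability table: AIT and AIP per
#' protocol and MAV between the protocols, in the standard 12-rotation
#' order, from the per-subject, per-trial normalised cycles.
#'
#' @param cycles_a,cycles_b nested lists: subject -> list of `gait_cycle`
#'   matrices (trials), for protocols A and B.  `cycles_b` may be `NULL`
#'   for a single-protocol report (AIT/AIP only).
#' @param protocol_names length-2 character, column naming.
#' @return Object of class `variability_report`: list with `table`
#'   (data.frame rotation x statistics), `sd_curves` (per protocol: subject
#'   -> 101 x 12 intertrial SD matrix), `subject_means`, `n_subjects`,
#'   `n_trials`.
#' @export
variability_report <- function(cycles_a, cycles_b = NULL,
                               protocol_names = c("isb6dof", "hh")) {
  one <- function(cycles) {
    sdc <- lapply(cycles, intertrial_sd_curve)
    means <- lapply(cycles, function(tr) {
      m <- ensemble_mean_sd(tr)$mean
      m
    })
    list(ait = average_intertrial_variability(sdc),
         aip = averaged_intraprotocol_variability(means),
         sd_curves = sdc, means = means)
  }
  a <- one(cycles_a)
  tab <- data.frame(rotation = rotation_labels(),
                    ait_a = unname(a$ait), aip_a = unname(a$aip))
  names(tab)[2:3] <- paste0(c("ait_", "aip_"), protocol_names[1])
  sd_curves <- stats::setNames(list(a$sd_curves), protocol_names[1])
  subject_means <- stats::setNames(list(a$means), protocol_names[1])
  if (!is.null(cycles_b)) {
    b <- one(cycles_b)
    tab[[paste0("ait_", protocol_names[2])]] <- unname(b$ait)
    tab[[paste0("aip_", protocol_names[2])]] <- unname(b$aip)
    tab$mav <- unname(mean_absolute_variability(a$means, b$means))
    sd_curves[[protocol_names[2]]] <- b$sd_curves
    subject_means[[protocol_names[2]]] <- b$means
  }
  structure(list(table = tab, sd_curves = sd_curves,
                 subject_means = subject_means,
                 n_subjects = length(cycles_a),
                 n_trials = lengths(cycles_a)),
            class = "variability_report")
}

#' @export
print.variability_report <- function(x, ...) {
  cat("variability report:", x$n_subjects, "subjects,",
      paste(unique(x$n_trials), collapse = "/"), "trials each\n")
  print(x$table, digits = 3, row.names = FALSE)
  invisible(x)
}
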