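# Shared fixtures: random poses, small marker sets, noise-free single-trial
# studies.  Everything is generated in code under fixed seeds.

random_pose <- function() {
  pose(random_rotations(1)[, , 1], stats::rnorm(3, 0, 100), check = FALSE)
}

# pose_series from a list of poses
as_pose_series <- function(poses) {
  n <- length(poses)
  R <- array(NA_real_, c(3, 3, n)); tr <- matrix(NA_real_, 3, n)
  for (q in seq_len(n)) {
    R[, , q] <- poses[[q]]$R; tr[, q] <- poses[[q]]$t
  }
  structure(list(R = R, t = tr, valid = rep(TRUE, n)),
            class = "pose_series")
}

small_mts <- function(n_frames = 10, labels = c("A", "B"), rate = 100,
                      seed = 1) {
  set.seed(seed)
  pos <- lapply(labels, function(l) matrix(rnorm(3 * n_frames, 0, 100),
                                           n_frames, 3))
  names(pos) <- labels
  marker_trajectory_set(pos, rate)
}

# one-subject, one-trial noise-free study (memoised: built once per run)
noise_free_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_study(simulation_config(
        n_subjects = 1, n_trials = 1, marker_noise_sd = 0,
        sigma_trial = 0, tau_subject = 0, seed = 42))
    cache
  }
})

# a 101 x 12 cycle matrix from a constant or function of t
cycle_matrix <- function(value = 0) {
  t <- seq(0, 1, length.out = 101)
  m <- if (is.function(value)) sapply(1:12, function(r) value(t, r)) else
    matrix(value, 101, 12)
  colnames(m) <- rotation_labels()
  m
}
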