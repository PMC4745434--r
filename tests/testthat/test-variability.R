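# independent brute-force oracles, written against plain loops
brute_sd_curves <- function(cycles) {
  out <- matrix(0, 101, 12)
  for (s in 1:101) for (r in 1:12) {
    v <- sapply(cycles, function(cy) cy[s, r])
    out[s, r] <- sqrt(sum((v - mean(v))^2) / (length(v) - 1))
  }
  colnames(out) <- rotation_labels()
  out
}

brute_ait <- function(sd_curves) {
  per <- sapply(sd_curves, function(s) {
    acc <- numeric(12)
    for (r in 1:12) acc[r] <- mean(s[, r])
    acc
  })
  rowMeans(per)
}

brute_mav <- function(a, b) {
  per <- sapply(names(a), function(s) {
    acc <- numeric(12)
    for (r in 1:12) acc[r] <- mean(abs(a[[s]][, r] - b[[s]][, r]))
    acc
  })
  rowMeans(per)
}

test_that("ensemble mean/SD match closed forms and brute force", {
  c0 <- cycle_matrix(function(t, r) 10 * sin(2 * pi * t) + r)
  same <- list(c0, c0, c0)
  es <- ensemble_mean_sd(same)
  expect_equal(es$mean, c0, ignore_attr = TRUE)
  expect_true(all(es$sd == 0))
  # two cycles offset by 2 deg: SD = sqrt(2) everywhere
  es2 <- ensemble_mean_sd(list(c0, c0 + 2))
  expect_equal(unname(es2$sd[1, 1]), sqrt(2), tolerance = 1e-12)
  expect_true(all(abs(es2$sd - sqrt(2)) < 1e-12))
  set.seed(61)
  rnd <- lapply(1:5, function(q) cycle_matrix(function(t, r)
    rnorm(101, r, 3)))
  es3 <- ensemble_mean_sd(rnd)
  expect_equal(es3$sd, brute_sd_curves(rnd), tolerance = 1e-12)
  expect_error(ensemble_mean_sd(rnd[1]), "at least 2")
})

test_that("intertrial SD refuses mixed subjects and matches ensemble SD", {
  c0 <- cycle_matrix(function(t, r) r * cos(2 * pi * t))
  t1 <- structure(c0, subject = "S01")
  t2 <- structure(c0 + 1, subject = "S01")
  t3 <- structure(c0 - 1, subject = "S02")
  expect_equal(intertrial_sd_curve(list(t1, t2)),
               ensemble_mean_sd(list(t1, t2))$sd)
  expect_error(intertrial_sd_curve(list(t1, t3)), "one subject")
  expect_true(all(intertrial_sd_curve(list(t1, t1)) == 0))
})

test_that("AIT and AIP follow their averaging definitions", {
  z <- matrix(0, 101, 12)
  expect_true(all(average_intertrial_variability(list(z)) == 0))
  s1 <- matrix(1, 101, 12); s3 <- matrix(3, 101, 12)
  expect_equal(unname(average_intertrial_variability(list(s1, s3))),
               rep(2, 12))
  set.seed(67)
  rnd <- lapply(1:4, function(q) matrix(abs(rnorm(101 * 12)), 101, 12))
  expect_equal(unname(average_intertrial_variability(rnd)),
               unname(brute_ait(rnd)), tolerance = 1e-12)
  expect_error(average_intertrial_variability(list()), "at least one")

  m0 <- cycle_matrix(0); m2 <- cycle_matrix(2)
  expect_equal(unname(averaged_intraprotocol_variability(list(m0, m2))),
               rep(sqrt(2), 12), tolerance = 1e-12)
  expect_error(averaged_intraprotocol_variability(list(m0)), "at least 2")
})

test_that("MAV is a symmetric, translation-aware comparison", {
  a <- list(S1 = cycle_matrix(function(t, r) r * sin(2 * pi * t)),
            S2 = cycle_matrix(function(t, r) r * cos(2 * pi * t)))
  expect_true(all(mean_absolute_variability(a, a) == 0))
  b <- lapply(a, function(m) {
    mm <- m + 5
    colnames(mm) <- rotation_labels()
    mm
  })
  expect_equal(unname(mean_absolute_variability(a, b)), rep(5, 12),
               tolerance = 1e-12)
  set.seed(71)
  c2 <- lapply(a, function(m) cycle_matrix(function(t, r) rnorm(101)))
  expect_equal(mean_absolute_variability(a, c2),
               mean_absolute_variability(c2, a), tolerance = 1e-12)
  expect_equal(unname(mean_absolute_variability(a, c2)),
               unname(brute_mav(a, c2)), tolerance = 1e-12)
  names(c2) <- c("S1", "S9")
  expect_error(mean_absolute_variability(a, c2), "unpaired")
})

test_that("range of motion follows closed forms and translation rules", {
  expect_equal(range_of_motion(rep(2, 101)), 0)
  t <- seq(0, 1, length.out = 101)
  s <- 10 * sin(2 * pi * t)
  expect_equal(range_of_motion(s), 20, tolerance = 1e-3)
  expect_equal(range_of_motion(s + 37), range_of_motion(s))
  m <- cycle_matrix(function(t, r) r * sin(2 * pi * t))
  rom <- range_of_motion(m)
  expect_equal(unname(rom["knee_int_ext"]), 2 * 9, tolerance = 1e-3)
})

test_that("variability recovery: AIT tracks sigma, AIP tracks the mixture", {
  # 60 replicate studies at the design scale (4 subjects x 3 trials,
  # sigma = 1, tau = 3): the intertrial spread is realised exactly by the
  # generator, the between-subject mixture sqrt(tau^2 + sigma^2/3) within
  # sampling error
  aits <- aips <- numeric(60)
  for (k in 1:60) {
    cfg <- simulation_config(seed = 1000 + k)
    sdc <- list(); sm <- list()
    for (j in 1:4) {
      trials <- lapply(1:3, function(i) {
        m <- generate_angle_curves(cfg, j, i)
        colnames(m) <- rotation_labels()
        m
      })
      sdc[[j]] <- intertrial_sd_curve(trials)
      sm[[sprintf("S%02d", j)]] <- ensemble_mean_sd(trials)$mean
    }
    aits[k] <- mean(average_intertrial_variability(sdc))
    aips[k] <- mean(averaged_intraprotocol_variability(sm))
  }
  expect_equal(mean(aits), 1.0, tolerance = 1e-9)
  expect_equal(mean(aips), sqrt(3^2 + 1 / 3), tolerance = 0.10)
})
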