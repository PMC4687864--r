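test_that("activity detection triggers on wheel motion and tiles 5-s blocks", {
  ## flat record at baseline: nothing to report
  idle <- generate_trial(tw_geom, tw_sensors, mouse = NULL, speed = 0,
                         duration = 3, seed = 1)
  expect_equal(nrow(detect_activity(idle)), 0)

  ## 12-s run flanked by idle periods
  prof <- data.frame(t = c(0, 2.9, 3, 15, 15.1, 18), rps = c(0, 0, 2, 2, 0, 0))
  mouse <- virtual_mouse(gait = canonical_gait("trot", 1 / 7, 0.4))
  rec <- generate_trial(tw_geom, tw_sensors, mouse, speed = prof,
                        duration = 18, seed = 6)
  act <- detect_activity(rec)
  expect_gte(nrow(act), 3)
  expect_true(all(act$end_s - act$start_s <= 5 + 1e-9))
  ## blocks tile the run contiguously
  expect_equal(act$start_s[-1], act$end_s[-nrow(act)])
  expect_lt(abs(act$start_s[1] - 3), 0.5)
  expect_gt(act$end_s[nrow(act)], 14)

  ## first trigger crossing matches a brute-force per-sample scan
  v <- rec$channels[, 5]
  fs <- rec$sample_rate
  first_cross <- NA
  for (i in seq(fs + 1, length(v))) {
    if (abs(v[i] - median(v[(i - fs):i])) > 0.2) { first_cross <- i; break }
  }
  expect_equal(act$start_s[1], (first_cross - 1) / fs, tolerance = 0.3)
})

test_that("calibration fits recover lines exactly and match the closed form", {
  ## noiseless synthetic line
  masses <- seq(0.001, 0.041, by = 0.01)
  tab <- data.frame(sensor = 0L, mass_kg = masses,
                    mean_voltage = 2.5 + 4 * masses * 9.81)
  cal <- fit_calibration(tab)
  expect_equal(cal$intercept, 2.5, tolerance = 1e-12)
  expect_equal(cal$slope, 4, tolerance = 1e-12)
  expect_equal(cal$r2, 1)

  ## closed-form least-squares oracle on noisy data
  set.seed(8)
  tab$mean_voltage <- tab$mean_voltage + rnorm(length(masses), 0, 0.01)
  cal <- fit_calibration(tab)
  force <- masses * 9.81
  slope_oracle <- cov(force, tab$mean_voltage) / var(force)
  expect_equal(cal$slope, slope_oracle, tolerance = 1e-10)
  expect_equal(cal$intercept,
               mean(tab$mean_voltage) - slope_oracle * mean(force),
               tolerance = 1e-10)

  ## simulator calibration set: R^2 above 0.9 on every sensor
  expect_true(all(tw_calibration$r2 > 0.9))
  expect_equal(nrow(tw_calibration), 9)

  expect_error(fit_calibration(tab[1:2, ]), "3 distinct masses")
  flat <- data.frame(sensor = 0L, mass_kg = masses, mean_voltage = 2.5)
  expect_error(fit_calibration(flat), "zero-variance")
})

test_that("drift estimation recovers the configured rate", {
  rec <- generate_trial(tw_geom, tw_sensors, mouse = NULL, speed = 0,
                        duration = 15.7 * 3600, seed = 5, sample_rate = 1)
  dr <- estimate_drift(rec)
  expect_equal(nrow(dr), 9)
  expect_true(all(abs(dr$drift_v_per_h / 0.00063 - 1) < 0.10))
  expect_true(all(!dr$flagged))

  ## zero drift: slope statistically indistinguishable from zero
  s0 <- sensor_model(drift_rate = 0)
  rec0 <- generate_trial(tw_geom, s0, mouse = NULL, speed = 0,
                         duration = 2 * 3600, seed = 6, sample_rate = 1)
  dr0 <- estimate_drift(rec0)
  expect_true(all(abs(dr0$drift_v_per_h) < 3 * dr0$se))

  ## strong drift raises the QC flag
  sbig <- sensor_model(drift_rate = 0.02)
  recb <- generate_trial(tw_geom, sbig, mouse = NULL, speed = 0,
                         duration = 2 * 3600, seed = 7, sample_rate = 1)
  expect_true(all(estimate_drift(recb)$flagged))

  short <- generate_trial(tw_geom, tw_sensors, mouse = NULL, speed = 0,
                          duration = 600, seed = 8, sample_rate = 1)
  expect_error(estimate_drift(short), "at least")
})

test_that("speed estimates apply the strut formula per minima pair", {
  rec <- generate_trial(tw_geom, tw_sensors, mouse = NULL, speed = 1.99,
                        duration = 4, seed = 9)
  sp <- estimate_speed(rec)
  ## rps = f / (4 s) identity on every row
  expect_equal(sp$rps, rec$sample_rate / (4 * sp$s_samples))
  expect_equal(sp$speed_mps, sp$rps * 0.25)
  expect_equal(mean(sp$rps), 1.99, tolerance = 0.02)

  ## fewer than 2 minima: no estimate
  still <- generate_trial(tw_geom, tw_sensors, mouse = NULL, speed = 0,
                          duration = 1, seed = 10)
  expect_equal(nrow(estimate_speed(still)), 0)
})

test_that("max-concatenation equals the per-sample brute-force maximum", {
  rec <- sim_trial("trot", 0.5, seed = 11, duration = 1)
  trace <- concatenate_max(rec, tw_calibration)
  cal <- tw_calibration
  n <- nrow(rec$channels)
  oracle <- numeric(n)
  for (i in seq_len(n)) {
    best <- -Inf
    for (j in 1:9) {
      f <- (rec$channels[i, j] - cal$intercept[j]) / cal$slope[j]
      if (f < 0) f <- 0
      if (f > best) best <- f
    }
    oracle[i] <- best
  }
  expect_equal(trace$force, oracle, tolerance = 1e-12)
  expect_true(all(trace$force >= 0))

  ## pointwise dominance over every calibrated channel
  for (j in 1:9) {
    fj <- pmax((rec$channels[, j] - cal$intercept[j]) / cal$slope[j], 0)
    expect_true(all(trace$force - fj >= -1e-12))
  }

  ## synchronous contacts on different pads: the larger force, not the sum
  gt <- rec$ground_truth
  peak_sum <- max(rowSums(gt$limb_forces))
  expect_lt(max(trace$force), 0.75 * peak_sum)
  expect_error(concatenate_max(rec, cal[1:5, ]), "missing sensors")
})

test_that("spline smoothing preserves structure and reduces noise", {
  ## constant trace is unchanged
  flat <- force_trace(seq(0, 1, by = 0.01), rep(2, 101), stage = "raw_max")
  expect_equal(smooth_trace(flat)$force, flat$force, tolerance = 1e-9)

  ## endpoints preserved exactly
  rec <- sim_trial("trot", 0.5, seed = 12, duration = 1)
  raw <- concatenate_max(rec, tw_calibration)
  spl <- smooth_trace(raw)
  expect_equal(spl$force[1], raw$force[1])
  expect_equal(spl$force[length(spl$force)],
               raw$force[length(raw$force)])

  ## smoothed trace is RMS-closer to the true limb force than the raw max
  truth <- apply(rec$ground_truth$limb_forces, 1, max)
  rms <- function(x) sqrt(mean(x^2))
  expect_lt(rms(spl$force - truth), rms(raw$force - truth))
  expect_error(smooth_trace(force_trace(1:3 / 10, rep(0, 3))), "4 samples")
})

test_that("force traces and calibration matrices round-trip through disk", {
  rec <- sim_trial("trot", 0.5, seed = 13, duration = 0.2)
  trace <- concatenate_max(rec, tw_calibration)
  path <- withr::local_tempfile(fileext = ".csv")
  write_force_trace(trace, path)
  back <- read_force_trace(path)
  expect_equal(back$force, trace$force, tolerance = 1e-8)
  expect_equal(back$stage, "raw_max")

  jpath <- withr::local_tempfile(fileext = ".json")
  write_calibration(tw_calibration, jpath)
  back_cal <- read_calibration(jpath)
  expect_equal(back_cal$slope, tw_calibration$slope)
  expect_equal(back_cal$sensor, tw_calibration$sensor)
})
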