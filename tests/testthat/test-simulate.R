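test_that("limb forces are half-sines carrying the pair's weight share", {
  mouse <- virtual_mouse(gait = canonical_gait("trot", 0.15, 0.4))
  ## zero outside the stance window
  expect_equal(limb_force_profile(mouse, "RF", 0.41), 0)
  expect_equal(limb_force_profile(mouse, "RF", 0.99), 0)
  expect_gt(limb_force_profile(mouse, "RF", 0.2), 0)

  ## each pair's stride-averaged force equals its bias share of body weight
  ## (numerical quadrature oracle)
  phases <- seq(0, 1, length.out = 20001)[-20001]
  for (pair in list(c("LF", "RF"), c("LH", "RH"))) {
    mean_force <- mean(limb_force_profile(mouse, pair[1], phases) +
                         limb_force_profile(mouse, pair[2], phases))
    beta <- if (pair[1] == "LF") 0.51 else 0.49
    expect_equal(mean_force, beta * 0.034 * 9.81, tolerance = 1e-3)
  }

  ## equal bias and duty factors give equal fore and hind peaks
  m_eq <- virtual_mouse(fore_hind_bias = c(fore = 0.5, hind = 0.5),
                        gait = canonical_gait("trot", 0.15, 0.4))
  expect_equal(max(limb_force_profile(m_eq, "LF", phases)),
               max(limb_force_profile(m_eq, "LH", phases)))
  expect_error(
    limb_force_profile(
      virtual_mouse(gait = gait_timings(
        c(LF = 0, RF = 0.5, LH = 0, RH = 0.5), 0.4, 0.15)),
      "ZZ", 0.1))
})

test_that("an unloaded wheel reads baseline within the noise band", {
  rec <- generate_trial(tw_geom, tw_sensors, mouse = NULL, speed = 0,
                        duration = 1, seed = 3)
  dev <- sweep(rec$channels, 2, tw_sensors$baseline, "-")
  expect_lt(max(abs(dev)), 5 * tw_sensors$noise_sd)
})

test_that("strut gaps produce the expected central-sensor minima", {
  rec <- generate_trial(tw_geom, tw_sensors, mouse = NULL, speed = 1,
                        duration = 5, seed = 1)
  sp <- estimate_speed(rec)
  ## 4 struts x 5 revolutions = 20 minima, 19 consecutive pairs
  expect_equal(nrow(sp), 19)
  expect_equal(mean(sp$rps), 1, tolerance = 0.02)
})

test_that("ground truth records the commanded speed in both unit systems", {
  rec <- generate_trial(tw_geom, tw_sensors, mouse = NULL, speed = 1.99,
                        duration = 1, seed = 1)
  expect_equal(mean(rec$ground_truth$linear_speed), 0.4975)
  expect_equal(mean(rec$ground_truth$rps), 1.99)
})

test_that("trials are deterministic given a seed", {
  a <- sim_trial("trot", 0.5, seed = 7, duration = 0.5)
  b <- sim_trial("trot", 0.5, seed = 7, duration = 0.5)
  expect_identical(a$channels, b$channels)
  c <- sim_trial("trot", 0.5, seed = 8, duration = 0.5)
  expect_false(identical(a$channels, c$channels))
})

test_that("over-fast rotation is rejected with advice", {
  expect_error(
    generate_trial(tw_geom, tw_sensors, mouse = NULL, speed = 120,
                   duration = 0.1, seed = 1),
    "sample rate")
})

test_that("summed limb forces average to body weight over whole strides", {
  for (gait in c("trot", "half_bound", "gallop")) {
    rec <- sim_trial(gait, 0.6, seed = 5, duration = 2)
    gt <- rec$ground_truth
    Ts <- gt$timings$stride_period
    fs <- rec$sample_rate
    n_strides <- floor(nrow(rec$channels) / (Ts * fs))
    idx <- seq_len(round(n_strides * Ts * fs))
    total <- rowSums(gt$limb_forces[idx, ])
    expect_equal(mean(total), 0.034 * 9.81, tolerance = 1e-3)
  }
})

test_that("pad-over-sensor map is consistent with the rotation direction", {
  rec <- generate_trial(tw_geom, tw_sensors, mouse = NULL, speed = 1,
                        duration = 0.9, seed = 2)
  pm <- rec$ground_truth$pad_over_sensor
  ## as the wheel turns, the pad index over a fixed sensor steps downward
  for (j in c(1, 5, 9)) {
    steps <- diff(pm[, j])
    steps <- steps[steps != 0]
    expect_true(all(steps %% 16 == 15))
  }
  ## and a pad entering the array visits sensors in increasing order
  visits <- apply(pm, 1, function(r) match(4, r))
  visits <- visits[!is.na(visits)]
  expect_true(all(diff(visits) >= 0))
})

test_that("calibration sets are linear with the configured gain", {
  tab <- generate_calibration_set(tw_geom, tw_sensors, seed = 12)
  ## mass 0 reads baseline
  tab0 <- generate_calibration_set(tw_geom, tw_sensors, masses = c(0, 0.02, 0.04),
                                   seed = 13)
  base_rows <- tab0[tab0$mass_kg == 0, ]
  expect_equal(base_rows$mean_voltage, tw_sensors$baseline, tolerance = 1e-3)

  for (s in unique(tab$sensor)) {
    rows <- tab[tab$sensor == s, ]
    fit <- stats::lm(mean_voltage ~ I(mass_kg * 9.81), data = rows)
    expect_gt(summary(fit)$r.squared, 0.9)
    ## recovered slope equals gain within 2% (least-squares oracle)
    expect_equal(unname(stats::coef(fit)[2]), tw_sensors$gain[s + 1],
                 tolerance = 0.02)
  }
  expect_error(generate_calibration_set(tw_geom, tw_sensors,
                                        masses = numeric(0)), "empty")
})

test_that("labelled cohorts honour their gait mix and seed contract", {
  one <- generate_labeled_cohort(10, gait_mix = c(trot = 1),
                                 seed = 21, duration = 0.25)
  expect_true(all(vapply(one, function(x) x$gait, "") == "trot"))

  n <- 200
  mix <- c(trot = 0.4, half_bound = 0.3, gallop = 0.2, creep = 0.1)
  coh <- generate_labeled_cohort(n, mix, seed = 22, duration = 0.25)
  counts <- table(factor(vapply(coh, function(x) x$gait, ""),
                         levels = names(mix)))
  for (g in names(mix)) {
    ## exact binomial 95% acceptance band
    lo <- qbinom(0.025, n, mix[[g]])
    hi <- qbinom(0.975, n, mix[[g]])
    expect_gte(counts[[g]], lo)
    expect_lte(counts[[g]], hi)
  }
  speeds <- vapply(coh, function(x) x$speed_mps, 0)
  expect_true(all(speeds >= 0.06 & speeds <= 0.90))
  ## stance fractions decrease with speed within a gait
  tr <- vapply(coh, function(x) x$gait, "") == "trot"
  expect_lt(cor(speeds[tr], vapply(coh[tr], function(x) x$duty_factor, 0)), 0)

  coh2 <- generate_labeled_cohort(n, mix, seed = 22, duration = 0.25)
  expect_identical(coh[[5]]$record$channels, coh2[[5]]$record$channels)
  expect_error(generate_labeled_cohort(5, gait_mix = numeric(0)), "empty")
})

test_that("voltage records round-trip through CSV with sidecar", {
  rec <- sim_trial("trot", 0.5, seed = 30, duration = 0.2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_voltage_record(rec, path)
  expect_true(file.exists(paste0(path, ".json")))
  back <- read_voltage_record(path)
  expect_equal(back$sample_rate, rec$sample_rate)
  expect_equal(unname(back$channels), unname(rec$channels), tolerance = 1e-8)
  expect_equal(back$geometry$n_pads, 16L)
})
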