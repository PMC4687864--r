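test_that("phase differences match their defining geometry", {
  trot <- gait_timings(c(LF = 0.5, RF = 0, LH = 0, RH = 0.5), 0.4, 0.15)
  pd <- phase_differences(trot)
  expect_equal(unname(pd[c("F", "R")]), c(0.5, 0.5))
  expect_equal(unname(pd[c("D1", "D2")]), c(0, 0))

  hb <- gait_timings(c(LF = 0.55, RF = 0.65, LH = 0, RH = 0), 0.4, 0.15)
  pd <- phase_differences(hb)
  expect_equal(unname(pd[["R"]]), 0)
  expect_equal(unname(pd[["F"]]), 0.10)
})

test_that("phase differences equal the brute-force circular oracle", {
  set.seed(71)
  for (i in 1:1000) {
    on <- stats::setNames(runif(4), c("LF", "RF", "LH", "RH"))
    g <- gait_timings(on, 0.4, 0.2)
    pd <- phase_differences(g)
    oracle <- function(a, b) min(abs(a - b), 1 - abs(a - b))
    expect_equal(unname(pd[["F"]]), oracle(on["LF"], on["RF"]))
    expect_equal(unname(pd[["R"]]), oracle(on["LH"], on["RH"]))
    expect_equal(unname(pd[["D1"]]), oracle(on["LF"], on["RH"]))
    expect_equal(unname(pd[["D2"]]), oracle(on["RF"], on["LH"]))
    expect_true(all(pd >= 0 & pd <= 0.5))
    ## swapping left and right within both girdles leaves pair distances
    swapped <- gait_timings(stats::setNames(
      on[c("RF", "LF", "RH", "LH")], c("LF", "RF", "LH", "RH")), 0.4, 0.2)
    expect_equal(phase_differences(swapped)[c("F", "R")], pd[c("F", "R")])
  }
})

test_that("t_diff follows its formula and falls along a trot-to-bound morph", {
  trot <- gait_timings(c(LF = 0.5, RF = 0, LH = 0, RH = 0.5), 0.4, 0.15)
  expect_equal(t_diff(trot), 0.5)
  ## R = 0, D1 = 0.45, D2 = 0.30
  hb <- gait_timings(c(LF = 0.45, RF = 0.30, LH = 0, RH = 0), 0.4, 0.15)
  expect_equal(t_diff(hb), -0.45)

  ## morph the hind offset from 0.5 (trot) to 0 (hind-synchronous)
  grid <- seq(0.5, 0.02, by = -0.02)
  td <- vapply(grid, function(s) {
    t_diff(gait_timings(c(LF = 0.5, RF = 0, LH = 0, RH = s), 0.4, 0.15))
  }, 0)
  expect_true(all(diff(td) < 0))
  ## brute-force oracle at each morph point
  oracle <- vapply(grid, function(s) {
    circ <- function(a, b) min(abs(a - b), 1 - abs(a - b))
    circ(0, s) - max(circ(0.5, s), circ(0, 0))
  }, 0)
  expect_equal(td, oracle)
})

test_that("t_diff is invariant to time shift and stride rescale", {
  base <- c(LF = 0.45, RF = 0.70, LH = 0, RH = 0.1)
  g0 <- gait_timings(base, 0.3, 0.15)
  for (shift in c(0.13, 0.5, 0.91)) {
    g1 <- gait_timings((base + shift) %% 1, 0.3, 0.15)
    expect_equal(t_diff(g1), t_diff(g0))
  }
  g2 <- gait_timings(base, 0.3, 0.45)
  expect_equal(t_diff(g2), t_diff(g0))
})

test_that("gait labelling follows the footfall-timing rules", {
  Ts <- 0.15
  ## diagonal pairs simultaneous -> trot
  lab <- label_gait(c(LF = 0.075, RF = 0, LH = 0, RH = 0.075), Ts)
  expect_equal(lab$category, "trot")
  expect_true(lab$symmetric_flag)
  ## hind onsets 0.010 s apart, girdle pairing minimal -> half-bound
  lab <- label_gait(c(LF = 0.070, RF = 0.100, LH = 0, RH = 0.010), Ts)
  expect_equal(lab$category, "half_bound")
  expect_false(lab$symmetric_flag)
  ## hind onsets 0.040 s apart -> gallop
  lab <- label_gait(c(LF = 0.125, RF = 0.175, LH = 0, RH = 0.040), 0.25)
  expect_equal(lab$category, "gallop")
  expect_error(label_gait(c(LF = 0, RF = 0, LH = 0, RH = 0), 0),
               "stride_period")
})

test_that("gait labelling agrees with an exhaustive rule-table oracle", {
  set.seed(99)
  Ts <- 0.15
  oracle <- function(on, Ts, sync = 0.025, tol = 0.08) {
    circ <- function(a, b) {
      d <- abs(a - b) %% Ts
      min(d, Ts - d)
    }
    d_fore <- circ(on[["LF"]], on[["RF"]])
    d_hind <- circ(on[["LH"]], on[["RH"]])
    d_diag <- min(circ(on[["LF"]], on[["RH"]]), circ(on[["RF"]], on[["LH"]]))
    d_pair <- min(d_fore, d_hind)
    if (abs(d_diag - d_pair) < tol * Ts) "creep"
    else if (d_diag < d_pair) "trot"
    else if (d_hind < sync) "half_bound"
    else "gallop"
  }
  for (i in 1:10000) {
    on <- stats::setNames(runif(4, 0, Ts), c("LF", "RF", "LH", "RH"))
    expect_identical(label_gait(on, Ts)$category, oracle(on, Ts))
  }
})

test_that("canonical gaits carry their own labels", {
  Ts <- 0.15
  for (g in c("trot", "half_bound", "creep")) {
    cg <- canonical_gait(g, Ts, 0.3)
    expect_equal(label_gait(cg$contact_onset * Ts, Ts)$category, g)
  }
  ## gallop's 0.18-stride hind split exceeds the 0.025-s synchrony bound
  ## only for stride periods above ~0.14 s
  cg <- canonical_gait("gallop", 0.16, 0.3)
  expect_equal(label_gait(cg$contact_onset * 0.16, 0.16)$category, "gallop")
})

test_that("Froude numbers and transition speeds match dynamic similarity", {
  m <- froude_model(leg_length = 0.026)
  expect_equal(froude_number(0.36, m), 0.5, tolerance = 0.02)
  expect_equal(froude_number(0, m), 0)
  expect_equal(froude_number(0.5, froude_model(leg_length = 0.025)),
               0.25 / (9.81 * 0.025), tolerance = 1e-12)

  v <- predict_transition_speeds(m)
  expect_equal(round(unname(v), 2), c(0.36, 0.51, 0.68))
  ## doubling leg length scales every speed by sqrt(2)
  v2 <- predict_transition_speeds(froude_model(leg_length = 0.052))
  expect_equal(unname(v2 / v), rep(sqrt(2), 3))
  ## round trip recovers the defining Froude numbers
  fr <- froude_number(v, m)
  expect_equal(unname(fr), unname(m$transition_froude), tolerance = 1e-12)
  expect_error(froude_model(leg_length = -1), "leg_length")
  expect_error(froude_number(-0.1, m), "non-negative")
})

test_that("gait timings validate their invariants", {
  expect_error(gait_timings(c(LF = 0.5, RF = 0, LH = 0), 0.4, 0.15),
               "RH")
  expect_error(gait_timings(c(LF = 1.2, RF = 0, LH = 0, RH = 0.5), 0.4, 0.15),
               "\\[0, 1\\)")
  expect_error(gait_timings(c(LF = 0.5, RF = 0, LH = 0, RH = 0.5), 1.4, 0.15),
               "stance")
  expect_error(gait_timings(c(LF = 0.5, RF = 0, LH = 0, RH = 0.5), 0.4, -1),
               "stride_period")
})

test_that("gait library and annotation tables round-trip", {
  lib <- list(trot = canonical_gait("trot"),
              half_bound = canonical_gait("half_bound", 0.13, 0.25))
  path <- withr::local_tempfile(fileext = ".json")
  write_gait_library(lib, path)
  back <- read_gait_library(path)
  expect_equal(back$trot$contact_onset, lib$trot$contact_onset)
  expect_equal(back$half_bound$stride_period, lib$half_bound$stride_period)

  ## annotation table: one stride of a trot at 0.15 s
  tab <- data.frame(
    limb = c("LF", "RF", "LH", "RH"),
    onset_s = c(0.075, 0, 0, 0.075),
    offset_s = c(0.135, 0.06, 0.06, 0.135),
    stride_id = 1L)
  csv <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(tab, csv, row.names = FALSE)
  strides <- read_footfall_annotations(csv)
  expect_length(strides, 1)
  pd <- phase_differences(strides[[1]])
  expect_equal(unname(pd[["D1"]]), 0)
})
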