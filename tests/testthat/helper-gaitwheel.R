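## shared fixtures, built once per test run

tw_geom <- wheel_geometry()
tw_sensors <- sensor_model()
tw_calibration <- fit_calibration(
  generate_calibration_set(tw_geom, tw_sensors, seed = 4242))

## speed-matched stride parameters mirroring the cohort rules
trial_timings <- function(gait, speed_mps) {
  f_str <- 4.2 + 4 * speed_mps
  if (gait == "creep") f_str <- 0.75 * f_str
  df <- switch(gait,
               trot = 0.64 - 0.36 * speed_mps,
               creep = 0.76 - 0.36 * speed_mps,
               0.38 - 0.16 * speed_mps)
  canonical_gait(gait, stride_period = 1 / f_str,
                 duty_factor = min(max(df, 0.2), 0.78))
}

sim_trial <- function(gait, speed_mps, seed, duration = 2,
                      sensors = tw_sensors) {
  mouse <- virtual_mouse(gait = trial_timings(gait, speed_mps))
  generate_trial(tw_geom, sensors, mouse,
                 speed = speed_mps / tw_geom$path_length,
                 duration = duration, seed = seed)
}

sim_splined <- function(gait, speed_mps, seed, duration = 2,
                        sensors = tw_sensors) {
  rec <- sim_trial(gait, speed_mps, seed, duration, sensors)
  smooth_trace(concatenate_max(rec, tw_calibration))
}

## synthetic half-sine train as a bare force trace (no simulator)
half_sine_train <- function(peak_phases, stance_frac, stride_period,
                            n_strides, amplitudes = 1, fs = 1000) {
  duration <- n_strides * stride_period
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  amplitudes <- rep_len(amplitudes, length(peak_phases))
  f <- rep(0, length(t))
  for (k in seq(-1, n_strides)) {
    for (i in seq_along(peak_phases)) {
      t_on <- (k + peak_phases[i]) * stride_period
      tc <- stance_frac * stride_period
      sel <- t >= t_on & t < t_on + tc
      f[sel] <- pmax(f[sel], amplitudes[i] * sin(pi * (t[sel] - t_on) / tc))
    }
  }
  force_trace(t, f, stage = "splined", sample_rate = fs)
}
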