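#' Wheel geometry
#'
#' Physical description of the instrumented saucer wheel: 16 running pads in
#' 4 groups of 4, separated by 4 support struts per revolution, passing over
#' an arc of 9 Hall sensors mounted in the base. The running path advances
#' `path_length` metres per revolution. Sensors are spaced one pad pitch
#' apart and indexed 0..8 in the direction of pad travel; the central sensor
#' (index 4) sits at the angular origin. `station_fore` and `station_hind`
#' are the lab angles (radians) at which the fore and hind feet of a mouse
#' running at the front midpoint strike the wheel; they bracket the sensor
#' array so fore contacts are read by low-index sensors and hind contacts by
#' high-index sensors.
#'
#' @param n_pads,pads_per_group,n_groups pad layout (must satisfy
#'   `n_pads = n_groups * pads_per_group`).
#' @param n_sensors number of Hall sensors in the base array.
#' @param n_struts_per_rev support struts (magnet-free gaps) per revolution.
#' @param path_length running-path length per revolution, metres.
#' @param strut_half_width angular half-width of a strut gap, radians.
#' @param station_fore,station_hind lab angles of foot placement, radians.
#' @return a `wheel_geometry` object.
#' @export
wheel_geometry <- function(n_pads = 16L, pads_per_group = 4L, n_groups = 4L,
                           n_sensors = 9L, n_struts_per_rev = 4L,
                           path_length = 0.25, strut_half_width = 0.06,
                           station_fore = -1.05, station_hind = 0.35) {
  if (n_pads != n_groups * pads_per_group) {
    stop("n_pads must equal n_groups * pads_per_group")
  }
  if (path_length <= 0) stop("path_length must be positive")
  pad_pitch <- 2 * pi / n_pads
  structure(list(
    n_pads = as.integer(n_pads), pads_per_group = as.integer(pads_per_group),
    n_groups = as.integer(n_groups), n_sensors = as.integer(n_sensors),
    n_struts_per_rev = as.integer(n_struts_per_rev),
    path_length = path_length,
    pad_pitch = pad_pitch,
    pad_angular_width = pad_pitch,
    sensor_positions = (seq_len(n_sensors) - 1 - (n_sensors - 1) / 2) * pad_pitch,
    strut_positions = (seq_len(n_struts_per_rev) - 1) *
      (2 * pi / n_struts_per_rev),
    strut_half_width = strut_half_width,
    station_fore = station_fore, station_hind = station_hind),
    class = "wheel_geometry")
}

#' Hall-sensor response model
#'
#' Linear voltage-force transfer for each sensor (the wheel is calibrated in
#' its linear regime), Gaussian read noise with `3 * noise_sd` matching the
#' instrument's 0.04 V noise band, a slow linear baseline drift, the 0.2 V
#' motion-trigger delta, and the voltage dip produced when a magnet-free
#' strut gap passes over a sensor.
#'
#' @param baseline unloaded output voltage per sensor (scalar recycled).
#' @param gain sensitivity, volts per newton (`> 0`; scalar recycled).
#' @param noise_sd Gaussian read-noise SD in volts (default 0.0133 so that
#'   3 sigma is about 0.04 V).
#' @param drift_rate baseline drift, volts per hour (default 0.00063).
#' @param trigger_delta motion-trigger threshold, volts (default 0.2).
#' @param strut_dip voltage drop when a strut gap is over a sensor, volts.
#' @param n_sensors number of sensors the scalars are recycled to.
#' @return a `sensor_model` object.
#' @export
sensor_model <- function(baseline = 2.5, gain = 5, noise_sd = 0.0133,
                         drift_rate = 0.00063, trigger_delta = 0.2,
                         strut_dip = 0.5, n_sensors = 9L) {
  if (any(gain <= 0)) stop("gain must be positive")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  structure(list(
    baseline = rep_len(baseline, n_sensors),
    gain = rep_len(gain, n_sensors),
    noise_sd = noise_sd, drift_rate = drift_rate,
    trigger_delta = trigger_delta, strut_dip = strut_dip),
    class = "sensor_model")
}

#' Virtual mouse
#'
#' @param mass body mass, kg (default 0.034).
#' @param fore_hind_bias length-2 fractions of body weight supported by the
#'   fore and hind pairs; must sum to 1 (default `c(fore = 0.51, hind = 0.49)`).
#' @param gait a [gait_timings()] object (default: canonical trot).
#' @param leg_length hip height, metres (default 0.026).
#' @return a `virtual_mouse` object.
#' @export
virtual_mouse <- function(mass = 0.034,
                          fore_hind_bias = c(fore = 0.51, hind = 0.49),
                          gait = canonical_gait("trot"),
                          leg_length = 0.026) {
  if (mass <= 0) stop("mass must be positive")
  if (abs(sum(fore_hind_bias) - 1) > 1e-9) {
    stop("fore_hind_bias fractions must sum to 1")
  }
  stopifnot(inherits(gait, "gait_timings"))
  structure(list(mass = mass,
                 fore_hind_bias = stats::setNames(fore_hind_bias,
                                                  c("fore", "hind")),
                 gait = gait, leg_length = leg_length),
            class = "virtual_mouse")
}

limb_pair <- function(limb) ifelse(limb %in% c("LF", "RF"), "fore", "hind")

## half-sine peak force for one limb: stride-averaged pair force equals the
## pair's bias share of body weight => F_peak = pi * beta * m * g / (4 * DF)
limb_peak_force <- function(mouse, limb, gravity = 9.81) {
  beta <- mouse$fore_hind_bias[[limb_pair(limb)]]
  df <- mouse$gait$stance_fraction[[limb]]
  pi * beta * mouse$mass * gravity / (4 * df)
}

#' Half-sine limb force at a stride phase
#'
#' Vertical GRF of one limb modelled as a half sine over its stance window:
#' zero outside the window, and peaking at mid-stance at
#' `pi * beta * m * g / (4 * duty_factor)` where `beta` is the limb's pair
#' bias share, so that each pair's stride-averaged force equals its share of
#' body weight.
#'
#' @param mouse a [virtual_mouse()].
#' @param limb one of `"LF"`, `"RF"`, `"LH"`, `"RH"`.
#' @param stride_phase phase(s) in `[0, 1)` (values outside are wrapped).
#' @param gravity m/s^2.
#' @return force in newtons (vectorised over `stride_phase`).
#' @export
limb_force_profile <- function(mouse, limb, stride_phase, gravity = 9.81) {
  stopifnot(inherits(mouse, "virtual_mouse"))
  limb <- match.arg(limb, LIMBS)
  df <- mouse$gait$stance_fraction[[limb]]
  if (df <= 0 || df >= 1) stop("duty factor must lie in (0, 1)")
  onset <- mouse$gait$contact_onset[[limb]]
  peak <- limb_peak_force(mouse, limb, gravity)
  u <- (stride_phase - onset) %% 1
  ifelse(u < df, peak * sin(pi * u / df), 0)
}

## resolve a speed specification (rps) to a per-sample vector
resolve_speed_profile <- function(speed, t) {
  if (is.function(speed)) {
    w <- speed(t)
  } else if (is.data.frame(speed)) {
    if (!all(c("t", "rps") %in% names(speed))) {
      stop("speed profile data.frame needs columns t and rps")
    }
    w <- stats::approx(speed$t, speed$rps, xout = t, rule = 2)$y
  } else if (is.numeric(speed) && length(speed) == 1L) {
    w <- rep(speed, length(t))
  } else {
    stop("speed must be a scalar rps, a data.frame(t, rps) or a function")
  }
  if (any(w < 0)) stop("speed profile must be non-negative")
  w
}

#' Simulate a raw wheel recording
#'
#' Runs a virtual mouse on the virtual wheel and returns the 9-channel raw
#' voltage record. Each limb's stance plants on the pad under its station
#' angle at contact onset and rides that pad across the sensor array; a
#' sensor reads `baseline + gain * force` for the pad currently over it,
#' dips by `strut_dip` whenever a magnet-free strut gap passes (4 per
#' revolution over the central sensor), and carries Gaussian noise and
#' linear drift. Two feet landing on one pad sum their forces. Deterministic
#' given `seed`.
#'
#' @param geometry a [wheel_geometry()].
#' @param sensors a [sensor_model()].
#' @param mouse a [virtual_mouse()]; use mass 0 via `NULL` for an unloaded
#'   wheel.
#' @param speed wheel speed in revolutions per second: scalar, a
#'   `data.frame(t, rps)` for a piecewise-linear profile, or a function of
#'   time.
#' @param duration record length, seconds.
#' @param seed integer RNG seed.
#' @param sample_rate samples per second (default 3000).
#' @param theta0 initial wheel angle, radians.
#' @param gravity m/s^2.
#' @return a `voltage_record`: list with `channels` (N x 9 voltage matrix),
#'   `sample_rate`, `t0`, `geometry`, and a `ground_truth` list (per-sample
#'   wheel speed, per-limb forces, pad-over-sensor map, stance events).
#' @export
generate_trial <- function(geometry = wheel_geometry(),
                           sensors = sensor_model(n_sensors = geometry$n_sensors),
                           mouse = virtual_mouse(),
                           speed = 2, duration = 2, seed = 1,
                           sample_rate = 3000, theta0 = NULL,
                           gravity = 9.81) {
  if (duration <= 0) stop("duration must be positive")
  set.seed(seed)
  fs <- sample_rate
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  w <- resolve_speed_profile(speed, t)

  ## pad must be over a sensor for >= 2 samples
  wmax <- max(w)
  if (wmax > 0 && fs * geometry$pad_pitch / (2 * pi * wmax) < 2) {
    stop("pad transit shorter than 2 samples; use a higher sample rate")
  }
  if (is.null(theta0)) theta0 <- geometry$pad_pitch / 2
  dt <- 1 / fs
  theta <- theta0 + 2 * pi * dt * c(0, cumsum(w[-n]))

  n_pads <- geometry$n_pads
  pitch <- geometry$pad_pitch
  pad_force <- matrix(0, nrow = n_pads, ncol = n)
  limb_forces <- matrix(0, nrow = n, ncol = 4L,
                        dimnames = list(NULL, LIMBS))
  events <- list()

  if (!is.null(mouse) && mouse$mass > 0) {
    gait <- mouse$gait
    Ts <- gait$stride_period
    theta_at <- function(tt) {
      ifelse(tt < 0, theta[1] + 2 * pi * w[1] * tt,
             stats::approx(t, theta, xout = tt, rule = 2)$y)
    }
    for (limb in LIMBS) {
      onset <- gait$contact_onset[[limb]]
      df <- gait$stance_fraction[[limb]]
      peak <- limb_peak_force(mouse, limb, gravity)
      station <- if (limb_pair(limb) == "fore") geometry$station_fore
                 else geometry$station_hind
      strides <- seq(-1, ceiling(duration / Ts))
      for (k in strides) {
        t_on <- (k + onset) * Ts
        t_off <- t_on + df * Ts
        if (t_off <= 0 || t_on >= duration) next
        pad <- (floor(((station - theta_at(t_on)) %% (2 * pi)) / pitch)) %%
          n_pads
        i0 <- max(1L, ceiling(t_on * fs) + 1L)
        i1 <- min(n, ceiling(t_off * fs))
        if (i1 < i0) next
        idx <- i0:i1
        f <- peak * sin(pi * (t[idx] - t_on) / (df * Ts))
        f[f < 0] <- 0
        pad_force[pad + 1L, idx] <- pad_force[pad + 1L, idx] + f
        limb_forces[idx, limb] <- limb_forces[idx, limb] + f
        events[[length(events) + 1L]] <-
          data.frame(limb = limb, stride = k, t_on = t_on, t_off = t_off,
                     pad = pad, peak = peak)
      }
    }
  }

  n_sensors <- geometry$n_sensors
  channels <- matrix(0, nrow = n, ncol = n_sensors,
                     dimnames = list(NULL, paste0("s", seq_len(n_sensors) - 1)))
  pad_map <- matrix(NA_integer_, nrow = n, ncol = n_sensors)
  drift_v <- sensors$drift_rate * t / 3600
  ## a strut gap over a sensor dips the voltage (no magnet overhead), but
  ## the dip is masked in proportion to any force on the pad read by that
  ## sensor: a loaded magnet's field dominates the sensor
  dip_half_force <- 0.003
  for (j in seq_len(n_sensors)) {
    phi <- (geometry$sensor_positions[j] - theta) %% (2 * pi)
    strut <- rep(FALSE, n)
    for (cpos in geometry$strut_positions) {
      d <- abs(((phi - cpos + pi) %% (2 * pi)) - pi)
      strut <- strut | (d < geometry$strut_half_width)
    }
    pad <- pmin(floor(phi / pitch), n_pads - 1)
    pad_map[, j] <- as.integer(pad)
    f_seen <- pad_force[cbind(pad + 1L, seq_len(n))]
    dip <- sensors$strut_dip * strut * (1 - f_seen / (f_seen + dip_half_force))
    channels[, j] <- sensors$baseline[j] + sensors$gain[j] * f_seen - dip +
      drift_v + stats::rnorm(n, sd = sensors$noise_sd)
  }

  structure(list(
    channels = channels,
    sample_rate = fs,
    t0 = 0,
    geometry = geometry,
    sensors = sensors,
    seed = seed,
    ground_truth = list(
      rps = w,
      linear_speed = w * geometry$path_length,
      theta = theta,
      limb_forces = limb_forces,
      pad_over_sensor = pad_map,
      stance_events = if (length(events)) do.call(rbind, events) else NULL,
      timings = if (!is.null(mouse)) mouse$gait else NULL,
      mouse = mouse)),
    class = "voltage_record")
}

#' @export
print.voltage_record <- function(x, ...) {
  n <- nrow(x$channels)
  cat(sprintf("voltage_record: %d channels x %d samples (%.2f s at %g Hz)\n",
              ncol(x$channels), n, n / x$sample_rate, x$sample_rate))
  if (!is.null(x$ground_truth)) {
    cat(sprintf("  simulated; mean wheel speed %.3f rps (%.3f m/s)\n",
                mean(x$ground_truth$rps),
                mean(x$ground_truth$linear_speed)))
  }
  invisible(x)
}

#' Record timestamps
#' @param record a `voltage_record`.
#' @return numeric vector of sample times in seconds.
#' @export
record_times <- function(record) {
  record$t0 + (seq_len(nrow(record$channels)) - 1) / record$sample_rate
}

#' Simulate a calibration data set
#'
#' Emulates the bench calibration of the wheel: identical masses attached to
#' every pad, the wheel rotated at constant speed, and the mean voltage per
#' sensor recorded for each mass. Means are taken over samples in which a
#' magnet pad is over the sensor (strut-gap dips excluded), so the recovered
#' slope of voltage against force equals the configured sensor gain.
#'
#' @param geometry a [wheel_geometry()].
#' @param sensors a [sensor_model()].
#' @param masses masses in kg (default spans 1-41 g).
#' @param seed integer RNG seed.
#' @param duration,rps,sample_rate rotation protocol per mass.
#' @param gravity m/s^2.
#' @return data.frame with columns `sensor` (0-based), `mass_kg`,
#'   `mean_voltage`.
#' @export
generate_calibration_set <- function(geometry = wheel_geometry(),
                                     sensors = sensor_model(n_sensors = geometry$n_sensors),
                                     masses = seq(0.001, 0.041, by = 0.005),
                                     seed = 1, duration = 5, rps = 1,
                                     sample_rate = 3000, gravity = 9.81) {
  if (length(masses) == 0) stop("mass list must not be empty")
  if (any(masses < 0)) stop("masses must be non-negative")
  set.seed(seed)
  fs <- sample_rate
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  theta <- geometry$pad_pitch / 2 + 2 * pi * rps * t
  n_sensors <- geometry$n_sensors
  ## per-sensor mask: magnet pad (not strut) over the sensor
  pad_present <- matrix(TRUE, n, n_sensors)
  for (j in seq_len(n_sensors)) {
    phi <- (geometry$sensor_positions[j] - theta) %% (2 * pi)
    for (cpos in geometry$strut_positions) {
      d <- abs(((phi - cpos + pi) %% (2 * pi)) - pi)
      pad_present[d < geometry$strut_half_width, j] <- FALSE
    }
  }
  out <- vector("list", length(masses))
  for (mi in seq_along(masses)) {
    m <- masses[mi]
    mv <- numeric(n_sensors)
    for (j in seq_len(n_sensors)) {
      v <- ifelse(pad_present[, j],
                  sensors$baseline[j] + sensors$gain[j] * m * gravity,
                  sensors$baseline[j] - sensors$strut_dip) +
        stats::rnorm(n, sd = sensors$noise_sd)
      mv[j] <- mean(v[pad_present[, j]])
    }
    out[[mi]] <- data.frame(sensor = seq_len(n_sensors) - 1L,
                            mass_kg = m, mean_voltage = mv)
  }
  do.call(rbind, out)
}

## speed-dependent stride parameters used by the cohort generator; the
## linear rules reproduce the observed span of mouse wheel running
## (stride frequency ~5.3 Hz at 0.31 m/s to ~8.3 Hz at 1.01 m/s, duty
## factor ~0.53 down to ~0.28 over the same range).
cohort_stride_frequency <- function(speed_mps, gait) {
  f <- 4.2 + 4.0 * speed_mps
  if (gait == "creep") f <- 0.75 * f
  f
}

## symmetric gaits keep grounded duty factors; asymmetric (galloping)
## gaits have aerial phases, so their stance fractions run lower
cohort_duty_factor <- function(speed_mps, gait) {
  df <- switch(gait,
               trot = 0.64 - 0.36 * speed_mps,
               creep = 0.76 - 0.36 * speed_mps,
               0.38 - 0.16 * speed_mps)
  min(max(df, 0.2), 0.78)
}

#' Simulate a labelled cohort of trials
#'
#' Generates a reproducible set of wheel recordings spanning the gait
#' categories, with ground-truth Hildebrand timings and labels. Speeds are
#' drawn uniformly within a gait-appropriate window of `speed_range`
#' (creeps slow, gallops and half-bounds fast); stride frequency rises and
#' stance fraction falls with speed.
#'
#' @param n_trials number of trials (`> 0`).
#' @param gait_mix named numeric of category probabilities over
#'   `creep`, `trot`, `gallop`, `half_bound` (normalised internally).
#' @param speed_range length-2 linear-speed range, m/s.
#' @param seed integer RNG seed.
#' @param duration per-trial record length, seconds.
#' @param geometry,sensors,sample_rate passed to [generate_trial()].
#' @param mass,fore_hind_bias mouse parameters.
#' @return list of trials; each has `record`, `label` (a `gait_label`),
#'   `timings`, `gait`, `speed_mps`, `duty_factor`, `stride_frequency`,
#'   `seed`.
#' @export
generate_labeled_cohort <- function(n_trials,
                                    gait_mix = c(trot = 0.4, half_bound = 0.3,
                                                 gallop = 0.2, creep = 0.1),
                                    speed_range = c(0.06, 0.90),
                                    seed = 1, duration = 2,
                                    geometry = wheel_geometry(),
                                    sensors = sensor_model(n_sensors = geometry$n_sensors),
                                    sample_rate = 3000,
                                    mass = 0.034,
                                    fore_hind_bias = c(fore = 0.51, hind = 0.49)) {
  if (n_trials <= 0) stop("n_trials must be positive")
  if (length(gait_mix) == 0 || sum(gait_mix) <= 0) stop("empty gait mix")
  gait_mix <- gait_mix / sum(gait_mix)
  bad <- setdiff(names(gait_mix), c("creep", "trot", "gallop", "half_bound"))
  if (length(bad)) stop("unknown gait categories: ", paste(bad, collapse = ", "))
  set.seed(seed)
  cats <- sample(names(gait_mix), n_trials, replace = TRUE, prob = gait_mix)
  lo <- speed_range[1]; hi <- speed_range[2]; span <- hi - lo
  windows <- list(
    creep      = c(lo, lo + 0.35 * span),
    trot       = c(lo + 0.20 * span, lo + 0.80 * span),
    gallop     = c(lo + 0.45 * span, hi),
    half_bound = c(lo + 0.45 * span, hi))
  speeds <- vapply(cats, function(g) stats::runif(1, windows[[g]][1],
                                                  windows[[g]][2]), 0)
  f_jit <- stats::rnorm(n_trials, 0, 0.03)
  df_jit <- stats::rnorm(n_trials, 0, 0.02)
  trial_seeds <- sample.int(2^30, n_trials)

  lapply(seq_len(n_trials), function(i) {
    g <- cats[i]; v <- speeds[i]
    f_str <- cohort_stride_frequency(v, g) * (1 + f_jit[i])
    df <- min(max(cohort_duty_factor(v, g) + df_jit[i], 0.2), 0.8)
    timings <- canonical_gait(g, stride_period = 1 / f_str, duty_factor = df)
    mouse <- virtual_mouse(mass = mass, fore_hind_bias = fore_hind_bias,
                           gait = timings)
    rec <- generate_trial(geometry, sensors, mouse,
                          speed = v / geometry$path_length,
                          duration = duration, seed = trial_seeds[i],
                          sample_rate = sample_rate)
    list(record = rec, label = gait_label(g), timings = timings, gait = g,
         speed_mps = v, duty_factor = df, stride_frequency = f_str,
         seed = trial_seeds[i])
  })
}
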