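#' Force trace container
#'
#' A uniformly sampled single-channel force time series produced by the
#' reconstruction pipeline, at one of three stages: `raw_max` (per-sample
#' maximum over calibrated sensors, floored at zero), `splined` (cubic-spline
#' smoothed), or `filtered` (selective two-peak spectral filter).
#'
#' @param time sample times, seconds (uniform).
#' @param force force values, newtons (or percent body weight).
#' @param stage one of `"raw_max"`, `"splined"`, `"filtered"`.
#' @param sample_rate Hz.
#' @param sensor optional 0-based index of the sensor contributing each
#'   sample (carried from max-concatenation for fore/hind attribution).
#' @return a `force_trace` object.
#' @export
force_trace <- function(time, force, stage = c("raw_max", "splined", "filtered"),
                        sample_rate = NULL, sensor = NULL) {
  stage <- match.arg(stage)
  if (length(time) != length(force)) stop("time and force lengths differ")
  if (stage == "raw_max" && any(force < -1e-9)) {
    stop("raw_max forces must be non-negative")
  }
  if (is.null(sample_rate)) {
    sample_rate <- 1 / stats::median(diff(time))
  }
  structure(list(time = time, force = force, stage = stage,
                 sample_rate = sample_rate, sensor = sensor),
            class = "force_trace")
}

#' @export
print.force_trace <- function(x, ...) {
  cat(sprintf("force_trace [%s]: %d samples at %g Hz, peak %.3g N\n",
              x$stage, length(x$force), x$sample_rate, max(x$force)))
  invisible(x)
}

## rolling baseline: median over the preceding `window_s`, evaluated on a
## coarse grid and carried forward between grid points
rolling_baseline <- function(v, fs, window_s = 1, hop_s = 0.25) {
  n <- length(v)
  hop <- max(1L, round(hop_s * fs))
  win <- max(1L, round(window_s * fs))
  grid <- seq(1L, n, by = hop)
  med <- vapply(grid, function(i) {
    stats::median(v[max(1L, i - win):i])
  }, 0)
  stats::approx(grid, med, xout = seq_len(n), method = "constant",
                rule = 2)$y
}

#' Detect activity intervals
#'
#' Opens an interval when the central sensor departs by more than the
#' trigger delta (0.2 V) from its rolling 1-s median baseline, closes it
#' when the signal has stayed within the trigger band for `hold_s`, and
#' chunks each interval into blocks of at most `block_s` seconds (the
#' instrument saves data in 5-s blocks).
#'
#' @param record a `voltage_record`.
#' @param trigger_delta trigger threshold, volts.
#' @param hold_s quiet time that closes an interval, seconds.
#' @param block_s maximum block length, seconds.
#' @param central_channel 1-based column index of the central sensor.
#' @return data.frame with columns `start_s`, `end_s`, `block` (empty when
#'   idle).
#' @export
detect_activity <- function(record, trigger_delta = 0.2, hold_s = 1,
                            block_s = 5,
                            central_channel = (ncol(record$channels) + 1) %/% 2) {
  v <- record$channels[, central_channel]
  fs <- record$sample_rate
  base <- rolling_baseline(v, fs)
  active <- abs(v - base) > trigger_delta
  if (!any(active)) {
    return(data.frame(start_s = numeric(0), end_s = numeric(0),
                      block = integer(0)))
  }
  ## close gaps shorter than hold_s, then take runs
  hold <- max(1L, round(hold_s * fs))
  r <- rle(active)
  idx <- which(!r$values & r$lengths < hold)
  idx <- idx[idx > 1 & idx < length(r$values)]
  r$values[idx] <- TRUE
  active <- inverse.rle(r)
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  tt <- record_times(record)
  out <- list()
  blk <- 0L
  for (k in runs) {
    t_start <- tt[starts[k]]
    t_end <- tt[ends[k]]
    edges <- seq(t_start, t_end, by = block_s)
    if (edges[length(edges)] < t_end) edges <- c(edges, t_end)
    for (b in seq_len(length(edges) - 1L)) {
      blk <- blk + 1L
      out[[blk]] <- data.frame(start_s = edges[b], end_s = edges[b + 1L],
                               block = blk)
    }
    if (length(edges) == 1L) {
      blk <- blk + 1L
      out[[blk]] <- data.frame(start_s = t_start, end_s = t_end, block = blk)
    }
  }
  do.call(rbind, out)
}

#' Fit the voltage-force calibration matrix
#'
#' Per-sensor least-squares line `voltage = intercept + slope * force`,
#' fitted to a table of applied masses and mean voltages (masses spanning
#' 1-41 g on the bench). The slope is in volts per newton.
#'
#' @param table data.frame with columns `sensor`, `mass_kg`, `mean_voltage`
#'   (as from [generate_calibration_set()]).
#' @param gravity m/s^2.
#' @return a `calibration_matrix`: data.frame with one row per sensor and
#'   columns `sensor`, `intercept`, `slope`, `r2`.
#' @export
fit_calibration <- function(table, gravity = 9.81) {
  need <- c("sensor", "mass_kg", "mean_voltage")
  if (!all(need %in% names(table))) {
    stop("calibration table must have columns: ", paste(need, collapse = ", "))
  }
  fits <- lapply(split(table, table$sensor), function(s) {
    if (length(unique(s$mass_kg)) < 3) {
      stop("need at least 3 distinct masses per sensor (sensor ",
           s$sensor[1], ")")
    }
    if (stats::sd(s$mean_voltage) == 0) {
      stop("zero-variance voltages for sensor ", s$sensor[1])
    }
    force <- s$mass_kg * gravity
    fit <- stats::lm(mean_voltage ~ force, data = data.frame(
      force = force, mean_voltage = s$mean_voltage))
    r2 <- 1 - sum(stats::residuals(fit)^2) /
      sum((s$mean_voltage - mean(s$mean_voltage))^2)
    data.frame(sensor = s$sensor[1],
               intercept = unname(stats::coef(fit)[1]),
               slope = unname(stats::coef(fit)[2]),
               r2 = r2)
  })
  out <- do.call(rbind, fits)
  rownames(out) <- NULL
  class(out) <- c("calibration_matrix", "data.frame")
  out
}

#' Estimate per-sensor baseline drift
#'
#' Linear trend of each sensor's voltage against time, in volts per hour,
#' from a slow (for example 1 Hz) recording at least one hour long. A QC
#' flag is raised when the absolute slope exceeds `qc_bound`.
#'
#' @param record a `voltage_record` spanning at least `min_hours`.
#' @param qc_bound drift QC bound, volts/hour (default 0.005).
#' @param min_hours minimum record duration in hours.
#' @return data.frame with columns `sensor`, `drift_v_per_h`, `se`,
#'   `flagged`.
#' @export
estimate_drift <- function(record, qc_bound = 0.005, min_hours = 1) {
  tt <- record_times(record)
  hours <- (tt[length(tt)] - tt[1]) / 3600
  if (hours < min_hours) {
    stop(sprintf("record spans %.2f h; need at least %g h", hours, min_hours))
  }
  th <- tt / 3600
  out <- lapply(seq_len(ncol(record$channels)), function(j) {
    fit <- stats::lm(record$channels[, j] ~ th)
    co <- summary(fit)$coefficients
    data.frame(sensor = j - 1L, drift_v_per_h = co[2, 1], se = co[2, 2],
               flagged = abs(co[2, 1]) > qc_bound)
  })
  do.call(rbind, out)
}

#' Estimate wheel speed from strut minima
#'
#' The support struts carry no magnet, so the central sensor's voltage dips
#' each time a strut gap passes over it -- four times per revolution. With
#' `s` samples between consecutive minima, the rotational speed is
#' `rps = f / (4 s)` where `f` is the sample rate; linear speed follows from
#' the running-path length per revolution.
#'
#' @param record a `voltage_record`.
#' @param window optional `c(start_s, end_s)` restriction.
#' @param dip_threshold minima must fall this far below the channel median
#'   (volts).
#' @param rps_max largest credible wheel speed; sets the minimum separation
#'   `f / (4 rps_max)` between accepted minima.
#' @param central_channel 1-based central sensor column.
#' @param path_length metres of running path per revolution.
#' @param qc_band relative band around the median minima spacing outside
#'   which an interval is treated as a missed or spurious minimum and
#'   dropped; `NULL` disables the check.
#' @return data.frame with one row per consecutive-minima pair: `t` (s,
#'   midpoint), `s_samples`, `rps`, `speed_mps`.
#' @export
estimate_speed <- function(record, window = NULL, dip_threshold = 0.1,
                           rps_max = 6,
                           central_channel = (ncol(record$channels) + 1) %/% 2,
                           path_length = record$geometry$path_length %||% 0.25,
                           qc_band = c(0.6, 1.6)) {
  fs <- record$sample_rate
  v <- record$channels[, central_channel]
  tt <- record_times(record)
  if (!is.null(window)) {
    keep <- tt >= window[1] & tt <= window[2]
    v <- v[keep]; tt <- tt[keep]
  }
  thr <- stats::median(v) - dip_threshold
  below <- v < thr
  if (!any(below)) {
    return(data.frame(t = numeric(0), s_samples = integer(0),
                      rps = numeric(0), speed_mps = numeric(0)))
  }
  r <- rle(below)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  mins <- vapply(runs, function(k) {
    i <- starts[k]:ends[k]
    i[which.min(v[i])]
  }, 0L)
  ## enforce minimum separation; keep the deeper of two close minima
  min_sep <- fs / (4 * rps_max)
  if (length(mins) > 1) {
    keep <- mins[1]
    for (m in mins[-1]) {
      last <- keep[length(keep)]
      if (m - last >= min_sep) {
        keep <- c(keep, m)
      } else if (v[m] < v[last]) {
        keep[length(keep)] <- m
      }
    }
    mins <- keep
  }
  if (length(mins) < 2) {
    return(data.frame(t = numeric(0), s_samples = integer(0),
                      rps = numeric(0), speed_mps = numeric(0)))
  }
  s <- diff(mins)
  tm <- (tt[mins[-length(mins)]] + tt[mins[-1]]) / 2
  ## QC: drop pairs spanning a missed or spurious minimum (interval far
  ## from the running typical spacing)
  if (!is.null(qc_band) && length(s) >= 4) {
    ok <- s >= qc_band[1] * stats::median(s) & s <= qc_band[2] * stats::median(s)
    s <- s[ok]; tm <- tm[ok]
  }
  rps <- fs / (4 * s)
  data.frame(t = tm, s_samples = s, rps = rps, speed_mps = rps * path_length)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Max-concatenated force trace
#'
#' Calibrates every channel to force (`(voltage - intercept) / slope`,
#' floored at zero: unloaded pads read baseline noise) and concatenates the
#' maximum value across sensors at each time point. When two feet load pads
#' over different sensors only the greater force enters the trace; two feet
#' on a single pad appear summed, inherited from the physics.
#'
#' @param record a `voltage_record`.
#' @param calibration a `calibration_matrix` from [fit_calibration()].
#' @param body_weight optional body weight in newtons; when given the trace
#'   is expressed in percent body weight.
#' @return a `force_trace` at stage `raw_max`, with per-sample contributing
#'   sensor indices in `$sensor`.
#' @export
concatenate_max <- function(record, calibration, body_weight = NULL) {
  n_sensors <- ncol(record$channels)
  if (!all((seq_len(n_sensors) - 1L) %in% calibration$sensor)) {
    stop("calibration is missing sensors: ",
         paste(setdiff(seq_len(n_sensors) - 1L, calibration$sensor),
               collapse = ", "))
  }
  cal <- calibration[match(seq_len(n_sensors) - 1L, calibration$sensor), ]
  forces <- sweep(record$channels, 2, cal$intercept, "-")
  forces <- sweep(forces, 2, cal$slope, "/")
  forces[forces < 0] <- 0
  best <- max.col(forces, ties.method = "first")
  f <- forces[cbind(seq_len(nrow(forces)), best)]
  if (!is.null(body_weight)) f <- 100 * f / body_weight
  force_trace(record_times(record), f, stage = "raw_max",
              sample_rate = record$sample_rate, sensor = best - 1L)
}

#' Cubic-spline smoothing of a raw-max trace
#'
#' Fits a cubic spline through knots placed at the junctions where the
#' contributing sensor changes and on a uniform grid between them (about
#' 375 knots per second at the native rate: far finer than any gait
#' structure, far coarser than the sensor noise). Each knot takes the local
#' mean of the samples within half a knot pitch, which suppresses the read
#' noise the interpolant would otherwise thread through; a shape-preserving
#' cubic (monotone Hermite) is used between knots so the stance-onset
#' corners do not ring. Endpoints are preserved.
#'
#' @param trace a `force_trace` at stage `raw_max`.
#' @param knot_spacing knot pitch in samples (default `sample_rate / 375`).
#' @return a `force_trace` at stage `splined` (sensor indices carried over).
#' @export
smooth_trace <- function(trace, knot_spacing = NULL) {
  stopifnot(inherits(trace, "force_trace"))
  x <- trace$force
  n <- length(x)
  if (n < 4) stop("need at least 4 samples to spline")
  if (is.null(knot_spacing)) {
    knot_spacing <- max(2L, round(trace$sample_rate / 375))
  }
  knots <- c(seq(1L, n, by = knot_spacing), n)
  if (!is.null(trace$sensor)) {
    knots <- c(knots, which(diff(trace$sensor) != 0) + 1L)
  }
  knots <- sort(unique(knots))
  if (length(knots) < 2) knots <- c(1L, n)
  h <- max(1L, knot_spacing %/% 2)
  vals <- vapply(knots, function(i) {
    mean(x[max(1L, i - h):min(n, i + h)])
  }, 0)
  ## endpoints preserved exactly
  vals[1] <- x[1]; vals[length(vals)] <- x[n]
  fn <- stats::splinefun(trace$time[knots], vals, method = "monoH.FC")
  force_trace(trace$time, fn(trace$time), stage = "splined",
              sample_rate = trace$sample_rate, sensor = trace$sensor)
}

#' Write / read a voltage record as CSV plus JSON sidecar
#'
#' The CSV has a `t` column and one `s0..s8` column per sensor; the sidecar
#' records sample rate, geometry, seed and a ground-truth summary.
#'
#' @param record a `voltage_record`.
#' @param path CSV path; the sidecar is written next to it as
#'   `<path>.json`.
#' @return `write_voltage_record` returns `path` invisibly;
#'   `read_voltage_record` returns a `voltage_record`.
#' @export
write_voltage_record <- function(record, path) {
  df <- data.frame(t = record_times(record), record$channels,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  gt <- record$ground_truth
  sidecar <- list(
    sample_rate = record$sample_rate,
    t0 = record$t0,
    seed = record$seed,
    geometry = record$geometry[c("n_pads", "pads_per_group", "n_groups",
                                 "n_sensors", "n_struts_per_rev",
                                 "path_length")],
    ground_truth_summary = if (!is.null(gt)) list(
      mean_rps = mean(gt$rps),
      mean_speed_mps = mean(gt$linear_speed),
      stride_period = gt$timings$stride_period %||% NULL) else NULL)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_voltage_record
#' @export
read_voltage_record <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"t" %in% names(df)) stop("record CSV must have a 't' column")
  sidecar_path <- paste0(path, ".json")
  sidecar <- if (file.exists(sidecar_path)) {
    jsonlite::read_json(sidecar_path)
  } else NULL
  fs <- sidecar$sample_rate %||% (1 / stats::median(diff(df$t)))
  geom <- if (!is.null(sidecar$geometry)) {
    do.call(wheel_geometry, sidecar$geometry[c("n_pads", "pads_per_group",
                                               "n_groups", "n_sensors",
                                               "n_struts_per_rev",
                                               "path_length")])
  } else wheel_geometry()
  structure(list(channels = as.matrix(df[setdiff(names(df), "t")]),
                 sample_rate = fs, t0 = df$t[1], geometry = geom,
                 sensors = NULL, seed = sidecar$seed,
                 ground_truth = NULL),
            class = "voltage_record")
}

#' Write / read a force trace as CSV
#'
#' @param trace a `force_trace`.
#' @param path CSV path (columns `t`, `force`, `stage`, optionally
#'   `sensor`).
#' @return `write_force_trace` returns `path` invisibly; `read_force_trace`
#'   returns a `force_trace`.
#' @export
write_force_trace <- function(trace, path) {
  df <- data.frame(t = trace$time, force = trace$force, stage = trace$stage)
  if (!is.null(trace$sensor)) df$sensor <- trace$sensor
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_force_trace
#' @export
read_force_trace <- function(path) {
  df <- utils::read.csv(path)
  force_trace(df$t, df$force, stage = df$stage[1],
              sensor = df$sensor %||% NULL)
}

#' Write / read a calibration matrix as JSON
#' @param calibration a `calibration_matrix`.
#' @param path JSON path.
#' @return `write_calibration` returns `path` invisibly;
#'   `read_calibration` returns a `calibration_matrix`.
#' @export
write_calibration <- function(calibration, path) {
  jsonlite::write_json(as.data.frame(calibration), path, digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  out <- as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  class(out) <- c("calibration_matrix", "data.frame")
  out
}
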