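## trapezoid-rule integral of y(t)
trapz <- function(t, y) {
  n <- length(t)
  if (n < 2) return(0)
  sum((y[-1] + y[-n]) * diff(t)) / 2
}

## indices of local maxima (flats collapsed to their start)
candidate_maxima <- function(x) {
  if (length(x) < 3) return(integer(0))
  dx <- diff(x)
  s <- sign(dx)
  for (i in seq_along(s)) if (s[i] == 0 && i > 1) s[i] <- s[i - 1]
  which(s[-length(s)] > 0 & s[-1] < 0) + 1L
}

## topographic prominence of candidate maxima: height above the higher of
## the two key saddles separating the peak from higher terrain; the global
## maximum gets its own height
peak_prominence <- function(x, cand) {
  vapply(seq_along(cand), function(k) {
    p <- cand[k]
    h <- x[p]
    left <- cand[cand < p & x[cand] > h]
    right <- cand[cand > p & x[cand] > h]
    saddle_l <- if (length(left)) min(x[max(left):p]) else min(x[1:p])
    saddle_r <- if (length(right)) min(x[p:min(right)]) else
      min(x[p:length(x)])
    if (!length(left) && !length(right)) return(h)
    key <- if (!length(left)) saddle_r
           else if (!length(right)) saddle_l
           else max(saddle_l, saddle_r)
    h - key
  }, 0)
}

## prominent local maxima of a contact-force segment: candidates above
## `height_thr` whose topographic prominence exceeds `prominence_min`
prominent_maxima <- function(x, height_thr, prominence_min) {
  cand <- candidate_maxima(x)
  cand <- cand[x[cand] > height_thr]
  if (length(cand) == 0) return(which.max(x))
  prom <- peak_prominence(x, cand)
  keep <- cand[prom > prominence_min]
  if (length(keep) == 0) which.max(x) else keep
}

#' Segment a trace into strides
#'
#' Divides the reconstructed gait signal into strides by identifying its
#' repeating features: force peaks are extracted, the peaks-per-stride
#' period is estimated from the dominant repeat of the inter-peak interval
#' (and peak-height) pattern, and stride boundaries are placed at every
#' period-th peak, anchored at the tallest peak of the first period. A
#' trace with no spectral periodicity (dominant non-DC magnitude below
#' twice the median bin magnitude) is rejected.
#'
#' @param trace a `force_trace` (typically stage `splined` or `filtered`).
#' @param period optional peaks-per-stride override.
#' @param ... passed to [peak_times()].
#' @return list with `boundaries` (stride boundary times, s), `periods`
#'   (per-stride durations), `peaks` (all peak times), and
#'   `peaks_per_stride`.
#' @export
segment_strides <- function(trace, period = NULL, ...) {
  stopifnot(inherits(trace, "force_trace"))
  X <- stats::fft(trace$force)
  hs <- half_spectrum(X)
  if (max(hs$mag) <= 2 * stats::median(hs$mag) + 1e-12) {
    stop("no periodicity detected in trace")
  }
  pk <- peak_times(trace, ...)
  d <- diff(pk)
  if (is.null(period)) period <- peaks_per_stride(d, attr(pk, "heights"))
  heights <- attr(pk, "heights")
  anchor <- which.max(heights[seq_len(min(period, length(heights)))])
  b_idx <- seq(anchor, length(pk), by = period)
  if (length(b_idx) < 2) stop("fewer than 2 stride boundaries found")
  boundaries <- as.numeric(pk[b_idx])
  list(boundaries = boundaries, periods = diff(boundaries),
       peaks = pk, peaks_per_stride = period)
}

#' Segment a stride window into stances
#'
#' Stance intervals are the contiguous regions where the force exceeds a
#' near-zero threshold (a fraction of the window's peak force). A region
#' containing several prominent peaks separated by deep troughs (below
#' `split_frac` of the lower adjacent peak) is split at those troughs into
#' per-contact stances; regions whose internal troughs stay shallow are
#' kept whole and flagged multi-peak, and are excluded from single-leg
#' statistics downstream. A window whose force never approaches zero is
#' returned as a single grounded interval with a flag.
#'
#' @param trace a `force_trace`.
#' @param window `c(start_s, end_s)` stride window (default: whole trace).
#' @param threshold_frac near-zero threshold as a fraction of the window's
#'   peak force (default 0.05).
#' @param split_frac troughs below this fraction of the lower adjacent peak
#'   split a multi-contact region (default 0.3).
#' @param prominence_frac minimum topographic prominence of a counted peak,
#'   as a fraction of the region's maximum (default 0.1).
#' @param min_duration_s regions shorter than this are discarded as noise
#'   blips (default 0.01 s).
#' @return data.frame with columns `start_s`, `end_s`, `duration_s`,
#'   `peak_force`, `peak_time`, `peak_sensor` (NA when unknown),
#'   `single_peak`, `grounded`.
#' @export
segment_stances <- function(trace, window = NULL, threshold_frac = 0.05,
                            split_frac = 0.3, prominence_frac = 0.1,
                            min_duration_s = 0.01) {
  stopifnot(inherits(trace, "force_trace"))
  tt <- trace$time
  sel <- if (is.null(window)) rep(TRUE, length(tt)) else
    tt >= window[1] & tt <= window[2]
  x <- trace$force[sel]
  t_w <- tt[sel]
  sens <- if (!is.null(trace$sensor)) trace$sensor[sel] else NULL
  empty <- data.frame(start_s = numeric(0), end_s = numeric(0),
                      duration_s = numeric(0), peak_force = numeric(0),
                      peak_time = numeric(0), peak_sensor = integer(0),
                      single_peak = logical(0), grounded = logical(0))
  if (length(x) == 0 || max(x) <= 0) return(empty)
  thr <- threshold_frac * max(x)
  above <- x > thr
  if (!any(above)) return(empty)
  grounded_all <- all(above)
  r <- rle(above)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  pieces <- list()
  for (k in runs) {
    i0 <- starts[k]; i1 <- ends[k]
    xi <- x[i0:i1]
    pks <- prominent_maxima(xi, height_thr = 0.3 * max(xi),
                            prominence_min = prominence_frac * max(xi))
    ## split at deep troughs between adjacent prominent peaks
    cuts <- integer(0)
    if (length(pks) > 1) {
      for (b in seq_len(length(pks) - 1L)) {
        seg <- pks[b]:pks[b + 1L]
        trough <- seg[which.min(xi[seg])]
        if (xi[trough] < split_frac * min(xi[pks[b]], xi[pks[b + 1L]])) {
          cuts <- c(cuts, trough)
        }
      }
    }
    bounds <- c(1L, cuts, length(xi) + 1L)
    for (g in seq_len(length(bounds) - 1L)) {
      seg <- bounds[g]:(bounds[g + 1L] - 1L)
      n_pk <- sum(pks >= seg[1] & pks <= seg[length(seg)])
      j <- (i0 - 1L) + seg
      j_pk <- j[which.max(x[j])]
      pieces[[length(pieces) + 1L]] <- list(
        j1 = j[1], j2 = j[length(j)], j_pk = j_pk,
        at_cut_left = g > 1L, at_cut_right = g < length(bounds) - 1L,
        ## a continuously loaded window counts as grounded only when no
        ## deep trough allowed it to be split into contacts
        grounded = grounded_all && length(cuts) == 0L,
        n_pk = n_pk)
    }
  }
  ## refine stance edges against the stance's own near-zero level: the
  ## window-wide threshold over-trims contacts weaker than the tallest one
  n_p <- length(pieces)
  for (p in seq_len(n_p)) {
    pc <- pieces[[p]]
    thr_own <- threshold_frac * x[pc$j_pk]
    if (!pc$at_cut_left) {
      lo <- if (p > 1L) pieces[[p - 1L]]$j2 + 1L else 1L
      while (pc$j1 > lo && x[pc$j1 - 1L] > thr_own) pc$j1 <- pc$j1 - 1L
    }
    if (!pc$at_cut_right) {
      hi <- if (p < n_p) pieces[[p + 1L]]$j1 - 1L else length(x)
      while (pc$j2 < hi && x[pc$j2 + 1L] > thr_own) pc$j2 <- pc$j2 + 1L
    }
    pieces[[p]] <- pc
  }
  out <- do.call(rbind, lapply(pieces, function(pc) {
    data.frame(
      start_s = t_w[pc$j1], end_s = t_w[pc$j2],
      duration_s = t_w[pc$j2] - t_w[pc$j1],
      peak_force = x[pc$j_pk], peak_time = t_w[pc$j_pk],
      peak_sensor = if (is.null(sens)) NA_integer_ else sens[pc$j_pk],
      single_peak = pc$n_pk <= 1L,
      grounded = pc$grounded)
  }))
  ## noise blips above threshold are not stances
  out[out$duration_s >= min_duration_s, , drop = FALSE]
}

#' Per-block stride kinematics
#'
#' Groups consecutive strides into blocks of `strides_per_block` (three, as
#' used for video synchronisation), and reports per-block mean stride
#' period, stance period (single-peak stances only), duty factor, stride
#' frequency, peak force and speed. Blocks over which the wheel speed
#' ranged more than `max_speed_swing` (1 revolution per second, 0.25 m/s)
#' are discarded to avoid accelerating or decelerating strides.
#'
#' @param trace a `force_trace` used for stance segmentation (typically
#'   `splined`).
#' @param strides a [segment_strides()] result (may come from a different
#'   stage of the same trace).
#' @param speeds data.frame with columns `t` and `speed_mps` (as from
#'   [estimate_speed()]).
#' @param strides_per_block strides per block (default 3).
#' @param max_speed_swing largest allowed speed range within a block, m/s.
#' @param threshold_frac stance near-zero threshold fraction.
#' @return data.frame, one row per retained block: `t_start`, `t_end`,
#'   `speed_mps`, `stride_period_s`, `stride_freq_hz`, `stance_period_s`,
#'   `duty_factor`, `peak_force`, `n_stances`, `n_multi_peak`.
#' @export
extract_kinematics <- function(trace, strides, speeds,
                               strides_per_block = 3L,
                               max_speed_swing = 0.25,
                               threshold_frac = 0.05) {
  b <- strides$boundaries
  n_strides <- length(b) - 1L
  if (n_strides < strides_per_block) {
    stop("no qualifying blocks: need at least ", strides_per_block,
         " strides")
  }
  n_blocks <- n_strides %/% strides_per_block
  rows <- list()
  for (k in seq_len(n_blocks)) {
    i0 <- (k - 1L) * strides_per_block + 1L
    t_start <- b[i0]; t_end <- b[i0 + strides_per_block]
    sp <- speeds$speed_mps[speeds$t >= t_start & speeds$t <= t_end]
    if (length(sp) == 0) next
    if (diff(range(sp)) > max_speed_swing) next
    st <- segment_stances(trace, c(t_start, t_end), threshold_frac)
    ## drop stances clipped by the block edges (blocks start and end on a
    ## force peak, so the edge contacts are half-stances)
    eps <- 2 / trace$sample_rate
    st <- st[st$start_s > t_start + eps & st$end_s < t_end - eps, ,
             drop = FALSE]
    single <- st[st$single_peak & !st$grounded, , drop = FALSE]
    stride_period <- (t_end - t_start) / strides_per_block
    rows[[length(rows) + 1L]] <- data.frame(
      t_start = t_start, t_end = t_end,
      speed_mps = mean(sp),
      stride_period_s = stride_period,
      stride_freq_hz = 1 / stride_period,
      stance_period_s = if (nrow(single)) mean(single$duration_s) else NA_real_,
      duty_factor = if (nrow(single)) mean(single$duration_s) / stride_period
                    else NA_real_,
      peak_force = if (nrow(single)) mean(single$peak_force) else NA_real_,
      n_stances = nrow(st),
      n_multi_peak = sum(!st$single_peak))
  }
  if (!length(rows)) stop("no qualifying blocks after speed-swing exclusion")
  do.call(rbind, rows)
}

#' Predicted half-sine peak force from duty factor
#'
#' Duty-factor force prediction: with vertical GRF modelled as a half sine
#' over the stance, impulse balance of a limb supporting its pair's share
#' `beta` of body weight gives a peak force of
#' `constant * beta * m * g / duty_factor`, with `constant = pi / 4` per
#' limb. The constant is exposed as a model parameter.
#'
#' @param mass body mass, kg.
#' @param pair_bias fraction of body weight supported by the limb's pair
#'   (fore 0.51, hind 0.49 for mice).
#' @param duty_factor stance period / stride period, in `(0, 1)`.
#' @param constant half-sine impulse-balance constant (default `pi / 4`).
#' @param gravity m/s^2.
#' @return a `force_prediction`: list with `body_weight_n`, `pair_bias`,
#'   `duty_factor`, `predicted_peak_n`, `predicted_peak_bw` (multiples of
#'   body weight).
#' @export
predict_peak_force <- function(mass, pair_bias, duty_factor,
                               constant = pi / 4, gravity = 9.81) {
  if (any(duty_factor <= 0 | duty_factor >= 1)) {
    stop("duty factor must lie in (0, 1)")
  }
  if (any(pair_bias <= 0 | pair_bias >= 1)) {
    stop("pair bias must lie in (0, 1)")
  }
  w <- mass * gravity
  peak <- constant * pair_bias * w / duty_factor
  structure(list(body_weight_n = w, pair_bias = pair_bias,
                 duty_factor = duty_factor,
                 predicted_peak_n = peak,
                 predicted_peak_bw = peak / w),
            class = "force_prediction")
}

#' @export
print.force_prediction <- function(x, ...) {
  cat(sprintf(
    "predicted peak force %.4g N (%.1f%% body weight) at duty factor %.2f\n",
    x$predicted_peak_n, 100 * x$predicted_peak_bw, x$duty_factor))
  invisible(x)
}

#' Hind:fore impulse ratio
#'
#' Attributes each stance of a half-bound-style trace to the fore or hind
#' pair and returns the ratio of hind-pair to fore-pair impulse per stride
#' (trapezoid rule). In a half-bound the hind feet land together on one pad
#' so each hind stance carries the whole pair, while the fore feet
#' contribute two stances per stride; the ratio is therefore the mean hind
#' stance impulse over twice the mean fore stance impulse, which is robust
#' to stances clipped at the ends of the analysed span. Attribution uses
#' the identity of the sensor reading the stance peak -- with the wheel
#' turning so pads travel from the low-index to the high-index end of the
#' array, fore contacts are read by low-index sensors and hind contacts by
#' high-index sensors -- falling back to 2-means clustering of peak
#' amplitudes (the merged hind-pair peak is the taller) when sensor
#' identities are absent.
#'
#' @param trace a `force_trace` (stage `splined` recommended) covering
#'   several strides.
#' @param strides optional [segment_strides()] result; impulses are summed
#'   over the span of complete strides when given.
#' @param fore_sensors,hind_sensors 0-based sensor index sets.
#' @param threshold_frac stance near-zero threshold fraction.
#' @return list with `ratio` (hind pair / fore pair, per stride),
#'   `fore_impulse` and `hind_impulse` (mean per-stance impulses, N s),
#'   `n_fore`, `n_hind`, `method` ("sensor" or "cluster").
#' @export
impulse_ratio <- function(trace, strides = NULL,
                          fore_sensors = 0:3, hind_sensors = 5:8,
                          threshold_frac = 0.05) {
  window <- if (!is.null(strides)) {
    c(strides$boundaries[1], strides$boundaries[length(strides$boundaries)])
  } else c(trace$time[1], trace$time[length(trace$time)])
  st <- segment_stances(trace, window, threshold_frac)
  st <- st[!st$grounded, , drop = FALSE]
  ## drop stances clipped at either end of the analysed span
  eps <- 2 / trace$sample_rate
  st <- st[st$start_s > window[1] + eps & st$end_s < window[2] - eps, ,
           drop = FALSE]
  if (nrow(st) < 2) stop("too few stances to attribute fore and hind")
  if (all(!is.na(st$peak_sensor))) {
    pair <- ifelse(st$peak_sensor %in% fore_sensors, "fore",
                   ifelse(st$peak_sensor %in% hind_sensors, "hind", NA))
    method <- "sensor"
  } else {
    pair <- rep(NA_character_, nrow(st))
    method <- "cluster"
  }
  if (any(is.na(pair))) {
    if (length(unique(st$peak_force)) < 2 ||
        stats::sd(st$peak_force) < 0.05 * mean(st$peak_force)) {
      stop("fore/hind attribution impossible: no distinguishable clusters")
    }
    km <- stats::kmeans(st$peak_force, centers = 2)
    hind_cl <- which.max(km$centers)
    pair <- ifelse(km$cluster == hind_cl, "hind", "fore")
    method <- "cluster"
  }
  imp <- vapply(seq_len(nrow(st)), function(i) {
    sel <- trace$time >= st$start_s[i] & trace$time <= st$end_s[i]
    trapz(trace$time[sel], trace$force[sel])
  }, 0)
  n_fore <- sum(pair == "fore"); n_hind <- sum(pair == "hind")
  if (n_fore == 0 || n_hind == 0) {
    stop("fore/hind attribution impossible: one pair has no stances")
  }
  fore <- mean(imp[pair == "fore"]); hind <- mean(imp[pair == "hind"])
  if (fore <= 0 || hind <= 0) {
    stop("fore/hind attribution impossible: one pair has no impulse")
  }
  list(ratio = hind / (2 * fore), fore_impulse = fore, hind_impulse = hind,
       n_fore = n_fore, n_hind = n_hind, method = method)
}
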