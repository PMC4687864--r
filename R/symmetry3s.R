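#' Times of force-trace peaks
#'
#' Local maxima of the trace exceeding `min_height_frac` of the global
#' maximum, with a minimum separation (closer maxima are merged keeping the
#' higher), refined to sub-sample precision by a parabolic fit around each
#' peak. At least four peaks are required for the symmetry metric to be
#' defined.
#'
#' @param trace a `force_trace` (any stage).
#' @param min_height_frac height threshold as a fraction of the global
#'   maximum (default 0.1).
#' @param min_separation_s minimum spacing between accepted peaks, seconds.
#' @param prominence_frac minimum topographic prominence of an accepted
#'   peak, as a fraction of the global maximum; ripples riding on a
#'   stance's slopes fall below it.
#' @param refine_window_s half-width of the parabolic refinement window,
#'   seconds.
#' @return strictly increasing numeric vector of peak times (seconds) with
#'   peak heights in attribute `heights`.
#' @export
peak_times <- function(trace, min_height_frac = 0.1,
                       min_separation_s = 0.015, prominence_frac = 0.1,
                       refine_window_s = 0.008) {
  stopifnot(inherits(trace, "force_trace"))
  x <- trace$force
  n <- length(x)
  fs <- trace$sample_rate
  cand <- candidate_maxima(x)
  thr <- min_height_frac * max(x)
  cand <- cand[x[cand] > thr]
  if (length(cand) == 0) stop("no peaks found in trace")
  prom <- peak_prominence(x, cand)
  cand <- cand[prom > prominence_frac * max(x)]
  if (length(cand) == 0) stop("no prominent peaks found in trace")
  ## enforce a minimum separation, keeping the higher
  min_sep <- max(1L, round(min_separation_s * fs))
  keep <- cand[1]
  for (i in cand[-1]) {
    last <- keep[length(keep)]
    if (i - last >= min_sep) keep <- c(keep, i)
    else if (x[i] > x[last]) keep[length(keep)] <- i
  }
  if (length(keep) < 4) {
    stop("fewer than 4 peaks; stride-signal symmetry undefined")
  }
  ## parabolic sub-sample refinement
  w <- max(2L, round(refine_window_s * fs))
  times <- vapply(keep, function(i) {
    lo <- max(1L, i - w); hi <- min(n, i + w)
    seg <- lo:hi
    fit <- stats::lm.fit(cbind(1, seg, seg^2), x[seg])
    b <- fit$coefficients
    vertex <- if (is.finite(b[3]) && b[3] < 0) -b[2] / (2 * b[3]) else i
    if (vertex < lo || vertex > hi) vertex <- i
    trace$time[1] + (vertex - 1) / fs
  }, 0)
  structure(times, heights = x[keep])
}

#' Peaks-per-stride period of an interval sequence
#'
#' Estimates how many force peaks make up one stride from the dominant
#' repeat of the inter-peak interval sequence: the smallest candidate
#' period whose lagged mean-square self-mismatch is indistinguishable from
#' the best one. A perfectly even train returns the minimum period of 2
#' (two contacts per stride, as in a square trot).
#'
#' @param d inter-peak intervals, seconds.
#' @param heights optional peak heights, used alongside the intervals.
#' @param p_max largest candidate period.
#' @return integer period (peaks per stride), at least 2.
#' @export
peaks_per_stride <- function(d, heights = NULL, p_max = 6L) {
  n <- length(d)
  p_hi <- min(p_max, floor(n / 2))
  if (p_hi < 2L) return(2L)
  ## an (almost) perfectly even train with (almost) even heights carries no
  ## repeat structure beyond the contact itself: two contacts per stride
  ## (interquartile spread: robust to a stray peak, but still sensitive to
  ## a structural short-short-long pattern)
  even_d <- stats::IQR(d) < 0.05 * stats::median(d)
  has_h <- !is.null(heights) && length(heights) == n + 1L &&
    mean(heights) > 0
  even_h <- !has_h || stats::IQR(heights) < 0.06 * stats::median(heights)
  if (even_d && even_h) return(2L)
  feats <- list(d / mean(d))
  if (has_h) feats$h <- heights[-1] / mean(heights)
  mism <- vapply(2:p_hi, function(p) {
    mean(vapply(feats, function(f) {
      m <- length(f)
      mean((f[1:(m - p)] - f[(1 + p):m])^2)
    }, 0))
  }, 0)
  ps <- 2:p_hi
  best <- min(mism)
  tol <- best + 0.25 * (stats::median(mism) - best) + 1e-12
  ps[which(mism <= tol)[1]]
}

#' Stride-signal symmetry (3S) score
#'
#' Quantifies the half-wave symmetry of the peak structure of a gait force
#' trace on a `[0, 1]` scale. The inter-peak intervals `d` are differenced
#' twice (producing the triangle/sawtooth wave and its second difference
#' `u`), and `u` is compared against a copy of itself circularly shifted by
#' half the peaks-per-stride period `P`:
#' `3S = MSE(u, shift(u, round(P/2))) / (4 mean(u^2))`, clipped to `[0, 1]`.
#' A trot-like alternation (triangle wave with equal peak and trough) is
#' perfectly half-wave antisymmetric and scores 1; a skewed sawtooth
#' (half-bound) scores low. Peak trains whose intervals are even to within
#' `degenerate_tol` (a square trot) score 1 by convention. The score is
#' invariant to time translation and positive time scaling.
#'
#' @param peaks peak times in seconds (as from [peak_times()]), at least 4.
#' @param period optional peaks-per-stride period; estimated with
#'   [peaks_per_stride()] when `NULL`.
#' @param degenerate_tol even-train tolerance: when the root-mean-square of
#'   the second difference is below this fraction of the mean interval the
#'   train is treated as perfectly regular (default 0.1).
#' @return score in `[0, 1]`, with the period used in attribute `period`.
#' @export
compute_3s <- function(peaks, period = NULL, degenerate_tol = 0.1) {
  if (length(peaks) < 4) stop("need at least 4 peak times")
  d <- diff(peaks)
  if (any(d <= 0)) stop("peak times must be strictly increasing")
  if (is.null(period)) {
    period <- peaks_per_stride(d, attr(peaks, "heights"))
  }
  w <- diff(d)
  u <- diff(w)
  if (length(u) < period) {
    stop("too few peaks for the estimated peaks-per-stride period")
  }
  if (sqrt(mean(u^2)) < degenerate_tol * mean(d)) {
    return(structure(1, period = period))
  }
  ## trim to a whole number of periods so the circular shift is consistent
  m <- (length(u) %/% period) * period
  if (m < period) m <- length(u)
  u <- u[seq_len(m)]
  h <- round(period / 2)
  us <- u[((seq_len(m) - 1 + h) %% m) + 1]
  score <- mean((u - us)^2) / (4 * mean(u^2))
  structure(min(max(score, 0), 1), period = period)
}

#' Calibrate the symmetric/asymmetric 3S threshold
#'
#' Sweeps candidate thresholds over the midpoints of consecutive sorted
#' unique scores and computes, at each, the proportion of truly symmetric
#' gaits called symmetric (specificity, in the instrument's sense) and the
#' proportion of truly asymmetric gaits called asymmetric (sensitivity).
#' The calibrated threshold is the sweep point where the two curves cross
#' (their absolute difference is minimal; ties resolved by accuracy, then by
#' the lower threshold). A sample is called symmetric when its score is
#' greater than or equal to the threshold.
#'
#' @param scores numeric 3S scores.
#' @param symmetric logical ground-truth labels (TRUE = symmetric gait).
#' @return a `threshold_calibration`: list with `threshold`,
#'   `accuracy_at_threshold`, and `curves` (data.frame of threshold,
#'   specificity, sensitivity, accuracy).
#' @export
calibrate_threshold <- function(scores, symmetric) {
  if (length(scores) != length(symmetric)) stop("length mismatch")
  symmetric <- as.logical(symmetric)
  if (length(unique(symmetric)) < 2) {
    stop("need both symmetric and asymmetric samples to calibrate")
  }
  u <- sort(unique(scores))
  taus <- if (length(u) > 1) (u[-1] + u[-length(u)]) / 2 else u
  taus <- c(min(u) - 1e-9, taus, max(u) + 1e-9)
  rows <- lapply(taus, function(tau) {
    call_sym <- scores >= tau
    data.frame(threshold = tau,
               specificity = mean(call_sym[symmetric]),
               sensitivity = mean(!call_sym[!symmetric]),
               accuracy = mean(call_sym == symmetric))
  })
  curves <- do.call(rbind, rows)
  gap <- abs(curves$specificity - curves$sensitivity)
  best <- which(gap == min(gap))
  best <- best[order(-curves$accuracy[best], curves$threshold[best])][1]
  structure(list(threshold = curves$threshold[best],
                 accuracy_at_threshold = curves$accuracy[best],
                 curves = curves),
            class = "threshold_calibration")
}

#' @export
print.threshold_calibration <- function(x, ...) {
  cat(sprintf("3S threshold %.4f (accuracy %.3f at crossing)\n",
              x$threshold, x$accuracy_at_threshold))
  invisible(x)
}

#' Regression of 3S on the timing asymmetry index
#'
#' Least-squares line and Pearson correlation of 3S scores against
#' `T_diff = R - max(D1, D2)` for samples with video-derived Hildebrand
#' timings; the fitted 3S value at `T_diff = 0` is the timing-equivalent
#' threshold.
#'
#' @param s3 numeric 3S scores (>= 10 values).
#' @param tdiff matching timing asymmetry indices.
#' @return list with `slope`, `intercept`, `r`, `p_value`,
#'   `s3_at_tdiff0`, `n`.
#' @export
tdiff_regression <- function(s3, tdiff) {
  if (length(s3) != length(tdiff)) stop("length mismatch")
  if (length(s3) < 10) stop("need at least 10 paired samples")
  if (stats::sd(tdiff) == 0 || stats::sd(s3) == 0) {
    stop("zero variance in scores or timing index")
  }
  fit <- stats::lm(s3 ~ tdiff)
  ct <- stats::cor.test(tdiff, s3)
  co <- unname(stats::coef(fit))
  list(slope = co[2], intercept = co[1],
       r = unname(ct$estimate), p_value = ct$p.value,
       s3_at_tdiff0 = co[1], n = length(s3))
}

#' Speed-continuum summary of gait observations
#'
#' Histograms the observation speeds, reports the proportion of 3S-symmetric
#' gaits per speed bin, flags local minima of the count histogram as
#' candidate boundaries between gait regions, and (when two or more
#' boundaries are found) fits per-region lines of 3S against speed.
#'
#' @param samples data.frame with columns `speed_mps`, `s3`, and
#'   `symmetric_call` (logical).
#' @param bin_width speed bin width, m/s (`> 0`).
#' @return list with `bins` (data.frame: bin_mid, n, n_symmetric,
#'   prop_symmetric), `boundary_speeds`, and `region_fits` (possibly NULL).
#' @export
continuum_summary <- function(samples, bin_width = 0.05) {
  if (bin_width <= 0) stop("bin width must be positive")
  need <- c("speed_mps", "s3", "symmetric_call")
  if (!all(need %in% names(samples))) {
    stop("samples must have columns: ", paste(need, collapse = ", "))
  }
  if (nrow(samples) < 1) stop("need at least one sample")
  lo <- floor(min(samples$speed_mps) / bin_width) * bin_width
  breaks <- seq(lo, max(samples$speed_mps) + bin_width, by = bin_width)
  bin <- cut(samples$speed_mps, breaks, right = FALSE, labels = FALSE)
  mids <- (breaks[-length(breaks)] + breaks[-1]) / 2
  tab <- do.call(rbind, lapply(sort(unique(bin)), function(b) {
    sel <- bin == b
    data.frame(bin_mid = mids[b], n = sum(sel),
               n_symmetric = sum(samples$symmetric_call[sel]),
               prop_symmetric = mean(samples$symmetric_call[sel]))
  }))
  ## interior local minima of the occupied-bin counts
  counts <- tab$n
  k <- length(counts)
  boundary <- if (k >= 3) {
    idx <- which(counts[2:(k - 1)] < counts[1:(k - 2)] &
                   counts[2:(k - 1)] < counts[3:k]) + 1L
    tab$bin_mid[idx]
  } else numeric(0)
  region_fits <- NULL
  if (length(boundary) >= 2) {
    edges <- c(-Inf, boundary[1], boundary[length(boundary)], Inf)
    region_fits <- lapply(seq_len(3), function(r) {
      sel <- samples$speed_mps >= edges[r] & samples$speed_mps < edges[r + 1]
      if (sum(sel) < 3 || stats::sd(samples$speed_mps[sel]) == 0) return(NULL)
      fit <- stats::lm(s3 ~ speed_mps, data = samples[sel, ])
      co <- unname(stats::coef(fit))
      list(region = r, intercept = co[1], slope = co[2], n = sum(sel))
    })
  }
  list(bins = tab, boundary_speeds = boundary, region_fits = region_fits)
}
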