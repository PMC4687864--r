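## half-spectrum bin magnitudes (excluding DC); bins are 1-based FFT indices
half_spectrum <- function(X) {
  N <- length(X)
  bins <- 2:(floor(N / 2) + 1L)
  list(bins = bins, mag = Mod(X[bins]))
}

#' Frequencies of the two largest non-DC spectral peaks
#'
#' Identifies the two largest magnitude bins of the FFT of the trace,
#' neglecting the DC component; ties are broken towards the lower
#' frequency.
#'
#' @param trace a `force_trace` (or numeric vector with attribute-free
#'   sampling given via `sample_rate`).
#' @param sample_rate Hz, required when `trace` is a bare numeric vector.
#' @return named numeric `c(f1, f2)` in Hz with `f1 <= f2`.
#' @export
dominant_frequencies <- function(trace, sample_rate = NULL) {
  x <- if (inherits(trace, "force_trace")) trace$force else trace
  fs <- if (inherits(trace, "force_trace")) trace$sample_rate else sample_rate
  if (is.null(fs)) stop("sample_rate required for a bare numeric trace")
  if (length(x) < 8) stop("trace too short (need >= 8 samples)")
  X <- stats::fft(x)
  hs <- half_spectrum(X)
  if (diff(range(hs$mag)) <= 1e-12 * max(hs$mag, 1e-300)) {
    stop("flat spectrum: dominant frequencies undecidable")
  }
  ord <- order(-hs$mag, hs$bins)
  top <- hs$bins[ord[1:2]]
  f <- (top - 1) * fs / length(x)
  stats::setNames(sort(f), c("f1", "f2"))
}

#' Selective two-peak spectral filter
#'
#' The very selective band-pass used to extract the periodic gait signal:
#' the trace's FFT is taken, the two highest non-DC magnitude peaks (and
#' their conjugate-symmetric partners about half the sample rate) are
#' retained along with DC, everything else is zeroed, the retained non-DC
#' coefficients are rescaled by a common factor so the total signal energy
#' is preserved (Parseval), and the inverse transform is returned as a real
#' series.
#'
#' @param trace a `force_trace` (any stage) or numeric vector.
#' @param sample_rate Hz, required for a bare numeric vector.
#' @param zero_dc drop the DC component instead of retaining it (strict
#'   alternative; by default DC is kept unscaled so the mean force stays
#'   meaningful).
#' @return list with `trace` (a `force_trace` at stage `filtered`) and
#'   `result` (a `spectral_filter_result`: kept frequencies, common scale
#'   factor, input/output energies).
#' @export
two_peak_filter <- function(trace, sample_rate = NULL, zero_dc = FALSE) {
  is_trace <- inherits(trace, "force_trace")
  x <- if (is_trace) trace$force else trace
  fs <- if (is_trace) trace$sample_rate else sample_rate
  if (is.null(fs)) stop("sample_rate required for a bare numeric trace")
  N <- length(x)
  if (N < 8) stop("trace too short (need >= 8 samples)")
  tt <- if (is_trace) trace$time else (seq_len(N) - 1) / fs

  make_trace <- function(y) {
    force_trace(tt, y, stage = "filtered", sample_rate = fs,
                sensor = if (is_trace) trace$sensor else NULL)
  }
  e_in <- sum(x^2)
  if (e_in == 0) {
    res <- structure(list(kept_frequencies = c(NA_real_, NA_real_),
                          scale_factor = 1,
                          input_energy = 0, output_energy = 0),
                     class = "spectral_filter_result")
    return(list(trace = make_trace(x), result = res))
  }
  X <- stats::fft(x)
  hs <- half_spectrum(X)
  ord <- order(-hs$mag, hs$bins)
  top <- sort(hs$bins[ord[1:2]])
  conj_bin <- function(b) as.integer(((N - (b - 1)) %% N) + 1)
  keep <- unique(c(top, vapply(top, conj_bin, 0L)))
  keep <- keep[keep != 1L]

  Y <- complex(real = rep(0, N), imaginary = rep(0, N))
  kept_energy <- sum(Mod(X[keep])^2)
  ## rescale kept non-DC coefficients by a common factor so the total
  ## spectral (Parseval) energy matches the input's
  total <- sum(Mod(X)^2)
  if (zero_dc) {
    target <- total
  } else {
    Y[1] <- X[1]
    target <- total - Mod(X[1])^2
  }
  scale <- if (kept_energy > 0) sqrt(target / kept_energy) else 1
  Y[keep] <- X[keep] * scale
  y <- Re(stats::fft(Y, inverse = TRUE)) / N
  res <- structure(list(
    kept_frequencies = stats::setNames((top - 1) * fs / N, c("f1", "f2")),
    scale_factor = scale,
    input_energy = e_in,
    output_energy = sum(y^2)),
    class = "spectral_filter_result")
  list(trace = make_trace(y), result = res)
}

#' @export
print.spectral_filter_result <- function(x, ...) {
  cat(sprintf(
    "two-peak filter: kept %.3g and %.3g Hz, scale %.4f, energy %.6g -> %.6g\n",
    x$kept_frequencies[1], x$kept_frequencies[2], x$scale_factor,
    x$input_energy, x$output_energy))
  invisible(x)
}
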