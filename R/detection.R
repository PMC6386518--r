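#' Uniformly sampled LFP trace
#'
#' @param samples Numeric vector of voltages (microvolts).
#' @param rate_hz Sampling rate; must exceed 1620 Hz so the 810 Hz
#'   stopband edge of the ripple-band filter lies below Nyquist.
#' @param layer Anatomical layer tag, `"pyramidale"` or `"radiatum"`.
#' @return Object of class `lfp_signal`.
#' @export
lfp_signal <- function(samples, rate_hz, layer = c("pyramidale", "radiatum")) {
  layer <- match.arg(layer)
  if (rate_hz <= 1620) stop("rate_hz must exceed 1620 Hz")
  if (!all(is.finite(samples))) stop("LFP samples must be finite")
  structure(list(samples = as.numeric(samples), rate_hz = rate_hz,
                 layer = layer), class = "lfp_signal")
}

#' @export
print.lfp_signal <- function(x, ...) {
  cat(sprintf("lfp_signal: %s, %.1f s at %g Hz\n", x$layer,
              length(x$samples) / x$rate_hz, x$rate_hz))
  invisible(x)
}

#' Detection parameters
#'
#' Holds every constant of the event-detection algorithm: the ripple-band
#' equiripple filter specification (stopband 0-140 Hz, passband
#' 150-800 Hz, stopband 810 Hz-Nyquist, stopband ripple 5.6e-4, passband
#' ripple 2.8e-2, giving error-minimisation weights 51.2 and 1), the
#' five-point (2.5 ms) RMS window, the 3.5 SD RMS threshold, the 6 ms
#' merge gap, the five-peak cycle criterion at 3 SD of the rectified
#' band-passed signal, and the spectral-validation bands (peak power above
#' 150 Hz must exceed peak power in 75-125 Hz).
#'
#' @param rms_window Samples in the sliding RMS window.
#' @param rms_threshold_sd RMS threshold in SDs above the mean RMS.
#' @param merge_gap_ms Events closer than this are merged.
#' @param min_peaks Minimum number of supra-threshold oscillation peaks.
#' @param peak_threshold_sd Peak threshold in SDs of the rectified
#'   band-passed signal.
#' @param validation_window_s FFT window for spectral validation.
#' @param ripple_band,control_band,upper_hz Spectral validation bands (Hz).
#' @return List of class `detection_params`.
#' @export
detection_params <- function(rms_window = 5L, rms_threshold_sd = 3.5,
                             merge_gap_ms = 6, min_peaks = 5L,
                             peak_threshold_sd = 3,
                             validation_window_s = 0.1,
                             ripple_band = 150, control_band = c(75, 125),
                             upper_hz = 600) {
  stopifnot(rms_window >= 1, rms_threshold_sd > 0, merge_gap_ms >= 0,
            min_peaks >= 1, peak_threshold_sd > 0)
  structure(list(rms_window = as.integer(rms_window),
                 rms_threshold_sd = rms_threshold_sd,
                 merge_gap_ms = merge_gap_ms, min_peaks = as.integer(min_peaks),
                 peak_threshold_sd = peak_threshold_sd,
                 validation_window_s = validation_window_s,
                 ripple_band = ripple_band, control_band = control_band,
                 upper_hz = upper_hz),
            class = "detection_params")
}

# filter cache keyed by sampling rate
.filter_cache <- new.env(parent = emptyenv())

ripple_filter_coef <- function(rate_hz) {
  key <- sprintf("fir_%g", rate_hz)
  if (!is.null(.filter_cache[[key]])) return(.filter_cache[[key]])
  nyq <- rate_hz / 2
  # order scaled so the 10 Hz transition bands are met at any valid rate
  ord <- 2L * ceiling(0.12 * rate_hz)
  h <- signal::remez(ord, c(0, 140, 150, 800, 810, nyq) / nyq,
                     c(0, 0, 1, 1, 0, 0), w = c(51.2, 1, 51.2),
                     ftype = "bandpass")
  .filter_cache[[key]] <- as.numeric(h)
  h
}

#' Band-pass filter an LFP trace into the ripple band
#'
#' Applies the 140-800 Hz linear-phase equiripple FIR filter with the
#' group delay compensated, so the output is aligned with the input and
#' the designed magnitude response is preserved exactly.
#'
#' @param lfp An [lfp_signal()] or numeric vector.
#' @param rate_hz Sampling rate, required when `lfp` is a bare vector.
#' @return Numeric vector, same length as the input.
#' @export
bandpass_ripple <- function(lfp, rate_hz = NULL) {
  if (inherits(lfp, "lfp_signal")) { x <- lfp$samples; rate_hz <- lfp$rate_hz }
  else x <- as.numeric(lfp)
  if (is.null(rate_hz)) stop("rate_hz required for bare numeric input")
  h <- ripple_filter_coef(rate_hz)
  if (length(x) < length(h))
    stop("signal shorter than the filter order (", length(h), " taps)")
  delay <- (length(h) - 1L) / 2L
  y <- fft_convolve(x, h)
  y[(delay + 1L):(delay + length(x))]
}

# linear convolution via FFT, zero-padded
fft_convolve <- function(x, h) {
  n <- length(x) + length(h) - 1L
  nfft <- stats::nextn(n, 2)
  X <- stats::fft(c(x, numeric(nfft - length(x))))
  H <- stats::fft(c(h, numeric(nfft - length(h))))
  Re(stats::fft(X * H, inverse = TRUE))[seq_len(n)] / nfft
}

#' Sliding root-mean-square
#'
#' Centred RMS over a short window (default five points, 2.5 ms at
#' 2 kHz); windows shrink at the edges so the output has the same length
#' as the input.
#'
#' @param x Numeric vector (typically the band-passed LFP).
#' @param window Window length in samples.
#' @return Non-negative numeric vector, same length as `x`.
#' @export
sliding_rms <- function(x, window = 5L) {
  n <- length(x)
  if (n == 0L) stop("empty input")
  if (window > n) stop("window longer than signal")
  cs <- cumsum(c(0, x^2))
  half <- window %/% 2
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  sqrt((cs[hi + 1L] - cs[lo]) / (hi - lo + 1L))
}

#' Candidate event intervals from an RMS trace
#'
#' Maximal runs where the RMS exceeds its mean by more than
#' `rms_threshold_sd` standard deviations; runs separated by gaps of at
#' most `merge_gap_ms` are merged. Mean and SD are computed over the
#' supplied trace, which should span one epoch.
#'
#' @param rms RMS trace (one epoch).
#' @param rate_hz Sampling rate.
#' @param params [detection_params()].
#' @return Two-column integer matrix of (start, end) sample indices;
#'   zero rows when nothing crosses threshold.
#' @export
detect_candidates <- function(rms, rate_hz, params = detection_params()) {
  thr <- mean(rms) + params$rms_threshold_sd * stats::sd(rms)
  above <- rms > thr
  iv <- runs_to_intervals(above)
  if (nrow(iv) == 0L) return(iv)
  merge_intervals(iv, gap = round(params$merge_gap_ms / 1000 * rate_hz))
}

runs_to_intervals <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  cbind(start = starts[keep], end = ends[keep])
}

#' Merge intervals separated by small gaps
#'
#' Intervals whose gap (start of one minus end of the previous) is at
#' most `gap` samples are merged; boundary inclusive. Idempotent.
#'
#' @param intervals Two-column (start, end) matrix, sorted by start.
#' @param gap Maximum gap in samples.
#' @return Merged (start, end) matrix.
#' @export
merge_intervals <- function(intervals, gap) {
  if (nrow(intervals) <= 1L) return(intervals)
  out <- intervals[1, , drop = FALSE]
  for (i in 2:nrow(intervals)) {
    if (intervals[i, 1] - out[nrow(out), 2] <= gap)
      out[nrow(out), 2] <- max(out[nrow(out), 2], intervals[i, 2])
    else out <- rbind(out, intervals[i, , drop = FALSE])
  }
  out
}

#' Oscillation-cycle criterion
#'
#' Keeps only intervals containing at least `min_peaks` oscillation
#' cycles: strict positive local maxima of the band-passed signal whose
#' amplitudes exceed `peak_threshold_sd` standard deviations of the
#' rectified band-passed signal (SD computed over the whole epoch). One
#' peak corresponds to one cycle, so a three-cycle transient cannot pass
#' a five-peak requirement.
#'
#' @param filtered Band-passed LFP of the epoch.
#' @param intervals Candidate (start, end) matrix.
#' @param params [detection_params()].
#' @return Subset of `intervals` passing the criterion.
#' @export
cycle_criterion <- function(filtered, intervals, params = detection_params()) {
  if (nrow(intervals) == 0L) return(intervals)
  thr <- params$peak_threshold_sd * stats::sd(abs(filtered))
  ok <- vapply(seq_len(nrow(intervals)), function(i) {
    seg <- filtered[intervals[i, 1]:intervals[i, 2]]
    if (length(seg) < 3L) return(FALSE)
    mid <- seg[2:(length(seg) - 1L)]
    peaks <- mid > seg[1:(length(seg) - 2L)] & mid > seg[3:length(seg)] &
      mid > thr
    sum(peaks) >= params$min_peaks
  }, logical(1))
  intervals[ok, , drop = FALSE]
}

#' Spectral validation of candidate events
#'
#' For each interval, the power spectrum of the 100 ms of raw LFP centred
#' on the interval's peak (maximum rectified band-passed amplitude) is
#' computed with a Hann taper, zero-padded to 1 s for a 1 Hz grid. The
#' event is kept only when the peak power above 150 Hz exceeds the peak
#' power between 75 and 125 Hz, rejecting fast-gamma contamination.
#' Intervals whose window would extend past the epoch are skipped with a
#' warning.
#'
#' @param raw Raw LFP samples of the epoch.
#' @param filtered Band-passed LFP of the epoch.
#' @param intervals Candidate (start, end) matrix.
#' @param rate_hz Sampling rate.
#' @param params [detection_params()].
#' @return Data frame: `start`, `end`, `peak` (sample indices),
#'   `peak_amp_uV`, `peak_freq_hz`.
#' @export
spectral_validation <- function(raw, filtered, intervals, rate_hz,
                                params = detection_params()) {
  out <- data.frame(start = integer(0), end = integer(0), peak = integer(0),
                    peak_amp_uV = numeric(0), peak_freq_hz = numeric(0))
  if (nrow(intervals) == 0L) return(out)
  half <- round(params$validation_window_s / 2 * rate_hz)
  skipped <- 0L
  for (i in seq_len(nrow(intervals))) {
    seg <- abs(filtered[intervals[i, 1]:intervals[i, 2]])
    pk <- intervals[i, 1] + which.max(seg) - 1L
    if (pk - half < 1L || pk + half > length(raw)) { skipped <- skipped + 1L; next }
    spec <- event_spectrum(raw[(pk - half):(pk + half)], rate_hz)
    hi <- spec$freq > params$ripple_band & spec$freq <= params$upper_hz
    lo <- spec$freq >= params$control_band[1] & spec$freq <= params$control_band[2]
    if (!any(hi) || max(spec$power[hi]) <= max(0, spec$power[lo], na.rm = TRUE))
      next
    out <- rbind(out, data.frame(
      start = intervals[i, 1], end = intervals[i, 2], peak = pk,
      peak_amp_uV = max(seg),
      peak_freq_hz = spec$freq[hi][which.max(spec$power[hi])]))
  }
  if (skipped > 0L)
    warning(skipped, " event(s) skipped: validation window outside epoch")
  out
}

# Hann-tapered power spectrum, zero-padded to a 1 s grid (>= 1 Hz bins)
event_spectrum <- function(x, rate_hz, pad_s = 1) {
  x <- x - mean(x)
  n <- length(x)
  w <- 0.5 * (1 - cos(2 * pi * seq(0, n - 1) / (n - 1)))
  nfft <- stats::nextn(max(n, round(pad_s * rate_hz)), 2)
  X <- stats::fft(c(x * w, numeric(nfft - n)))
  nf <- nfft %/% 2
  list(freq = (seq_len(nf) - 1L) * rate_hz / nfft,
       power = Mod(X[seq_len(nf)])^2)
}

#' Detect high-frequency oscillation events in a session
#'
#' Runs the full detection chain epoch by epoch: ripple-band filtering,
#' sliding RMS, 3.5 SD thresholding with 6 ms merging, the five-peak
#' cycle criterion, and spectral validation. Threshold statistics (RMS
#' mean/SD and the rectified-signal SD) are computed per epoch, so
#' state-dependent baselines do not bleed across epochs.
#'
#' @param lfp Pyramidal-layer [lfp_signal()].
#' @param epochs Data frame with `label`, `start_s`, `end_s`.
#' @param params [detection_params()].
#' @return Data frame of class `hfo_events`: `event_id`, `epoch`,
#'   `start_s`, `end_s`, `peak_time_s`, `peak_amp_uV`, `peak_freq_hz`.
#' @export
detect_hfo <- function(lfp, epochs = NULL, params = detection_params()) {
  stopifnot(inherits(lfp, "lfp_signal"))
  fs <- lfp$rate_hz
  n <- length(lfp$samples)
  if (is.null(epochs))
    epochs <- data.frame(label = "session", start_s = 0, end_s = n / fs)
  filt <- bandpass_ripple(lfp)
  res <- vector("list", nrow(epochs))
  for (i in seq_len(nrow(epochs))) {
    i0 <- max(1L, floor(epochs$start_s[i] * fs) + 1L)
    i1 <- min(n, floor(epochs$end_s[i] * fs))
    f <- filt[i0:i1]
    rms <- sliding_rms(f, params$rms_window)
    iv <- detect_candidates(rms, fs, params)
    iv <- cycle_criterion(f, iv, params)
    ev <- spectral_validation(lfp$samples[i0:i1], f, iv, fs, params)
    if (nrow(ev)) {
      res[[i]] <- data.frame(
        epoch = i, start_s = (i0 - 1L + ev$start - 1L) / fs,
        end_s = (i0 - 1L + ev$end - 1L) / fs,
        peak_time_s = (i0 - 1L + ev$peak - 1L) / fs,
        peak_amp_uV = ev$peak_amp_uV, peak_freq_hz = ev$peak_freq_hz)
    }
  }
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(epoch = integer(0), start_s = numeric(0),
                      end_s = numeric(0), peak_time_s = numeric(0),
                      peak_amp_uV = numeric(0), peak_freq_hz = numeric(0))
  out <- cbind(event_id = seq_len(nrow(out)), out)
  class(out) <- c("hfo_events", "data.frame")
  out
}

#' Coefficient of variation of event peak amplitudes
#'
#' Session-level amplitude variability: SD over mean of the peak
#' band-passed amplitudes. Sessions with two co-occurring event
#' populations (ripple-like and pHFO) show larger values than
#' single-population control sessions. Requires at least `min_n` events.
#'
#' @param amps Numeric vector of peak amplitudes, or an `hfo_events`
#'   data frame (column `peak_amp_uV` is used).
#' @param min_n Minimum number of events.
#' @return SD/mean, a non-negative scalar.
#' @export
amplitude_cv <- function(amps, min_n = 20L) {
  if (is.data.frame(amps)) amps <- amps$peak_amp_uV
  if (length(amps) < min_n)
    stop("amplitude CV requires at least ", min_n, " events (got ",
         length(amps), ")")
  stats::sd(amps) / mean(amps)
}
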