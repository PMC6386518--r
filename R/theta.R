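# analytic signal via frequency-domain construction (one-sided spectrum)
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Clip the interictal-spike artifact out of a peri-event segment
#'
#' Replaces the central 200 ms of a 4 s radiatum segment with the mean of
#' the whole recording, removing the large interictal voltage deflection
#' that would otherwise smear the time-frequency representation.
#'
#' @param segment Numeric vector, exactly 4 s of LFP.
#' @param session_mean Mean of the full recording (microvolts).
#' @param rate_hz Sampling rate.
#' @param clip_s Width of the clipped centre (s).
#' @return The clipped segment.
#' @export
clip_event_artifact <- function(segment, session_mean, rate_hz,
                                clip_s = 0.2) {
  n <- length(segment)
  if (abs(n - 4 * rate_hz) > 1)
    stop("segment must be exactly 4 s long (got ", n / rate_hz, " s)")
  half <- round(clip_s / 2 * rate_hz)
  ctr <- n %/% 2
  segment[(ctr - half + 1L):(ctr + half)] <- session_mean
  segment
}

#' Morlet-wavelet time-frequency power
#'
#' Continuous wavelet transform with complex Morlet wavelets (default six
#' cycles) over 4-20 Hz. Wavelets are L1-normalised, so a sinusoid of
#' amplitude A produces power approximately A^2 at its frequency; power is
#' the squared magnitude of the wavelet coefficients, unnormalised across
#' frequencies.
#'
#' @param x Numeric signal (microvolts).
#' @param rate_hz Sampling rate.
#' @param freqs Frequency grid (Hz), spacing at most 0.5 Hz over 4-20 Hz.
#' @param n_cycles Wavelet width in cycles.
#' @return Matrix `length(freqs)` x `length(x)` of power (uV^2), with
#'   `freqs` attached as the `freqs` attribute.
#' @export
morlet_power <- function(x, rate_hz, freqs = seq(4, 20, by = 0.5),
                         n_cycles = 6) {
  n <- length(x)
  nfft <- stats::nextn(2 * n, 2)
  X <- stats::fft(c(x, numeric(nfft - n)))
  out <- matrix(0, length(freqs), n)
  for (k in seq_along(freqs)) {
    f <- freqs[k]
    sd_t <- n_cycles / (2 * pi * f)
    hw <- min(ceiling(4 * sd_t * rate_hz), n)
    tt <- (-hw:hw) / rate_hz
    w <- exp(2i * pi * f * tt) * exp(-tt^2 / (2 * sd_t^2))
    w <- w / sum(Mod(w))                    # L1 norm; |coef| ~ amplitude
    W <- stats::fft(c(w, complex(real = numeric(nfft - length(w)))))
    conv <- stats::fft(X * W, inverse = TRUE) / nfft
    out[k, ] <- Mod(conv[(hw + 1L):(hw + n)])^2 * 4
  }
  attr(out, "freqs") <- freqs
  out
}

#' Mean theta power in the peri-event windows
#'
#' Averages 7-11 Hz wavelet power over three windows relative to the
#' event: baseline (2.0 to 1.0 s before), before (0.6 to 0.1 s before)
#' and after (0.1 to 0.6 s after).
#'
#' @param power Time-frequency matrix from [morlet_power()] of the 4 s
#'   segment centred on the event.
#' @param rate_hz Sampling rate.
#' @param band Frequency band to average (Hz).
#' @return Named numeric: `baseline`, `before`, `after` (uV^2).
#' @export
theta_power_windows <- function(power, rate_hz, band = c(7, 11)) {
  freqs <- attr(power, "freqs")
  n <- ncol(power)
  ctr <- n %/% 2 + 1L
  rows <- freqs >= band[1] & freqs <= band[2]
  win <- function(a, b) {                   # seconds relative to event
    i0 <- ctr + round(a * rate_hz); i1 <- ctr + round(b * rate_hz)
    if (i0 < 1L || i1 > n) stop("window outside segment")
    mean(power[rows, i0:i1])
  }
  c(baseline = win(-2, -1), before = win(-0.6, -0.1), after = win(0.1, 0.6))
}

#' Mean running speed in the peri-event windows
#'
#' Same three windows as [theta_power_windows()], computed from the
#' tracked speed series.
#'
#' @param track Position track with `time_s` and `speed_cm_s`.
#' @param event_time Event time (s).
#' @return Named numeric: `baseline`, `before`, `after` (cm/s).
#' @export
speed_windows <- function(track, event_time) {
  win <- function(a, b) {
    sel <- track$time_s >= event_time + a & track$time_s <= event_time + b
    if (!any(sel)) stop("no tracking samples in peri-event window")
    mean(track$speed_cm_s[sel])
  }
  c(baseline = win(-2, -1), before = win(-0.6, -0.1), after = win(0.1, 0.6))
}

#' Theta phase at pHFO onset by causal/zero-phase extrapolation
#'
#' Estimates the theta phase at which an interictal-spike/pHFO complex is
#' initiated. The 2 s of radiatum LFP preceding the event are truncated
#' at the spike onset (located automatically as the last time the signal
#' departs from baseline by more than 2 SD and stays departed until the
#' spike peak). The truncated signal is band-passed at 4-12 Hz with both
#' a zero-phase and a causal Butterworth filter; instantaneous phases
#' come from the analytic signal. The zero-phase filter gives correct
#' phases but is contaminated near the truncation point, while the causal
#' filter is valid up to the end but carries the kernel's phase lag; the
#' constant offset between the two is estimated over the unperturbed
#' interior and used to correct the causal phase, which is then fitted
#' linearly over the last six theta cycles and extrapolated to the
#' truncation point. Phase 0 corresponds to the theta peak and increases
#' with time; values lie in [-pi, pi).
#'
#' Events whose interictal spike does not exceed `spike_threshold_sd`
#' standard deviations of the first second are excluded, as are segments
#' with fewer than six theta cycles before onset.
#'
#' @param segment 2 s of radiatum LFP ending at (and including) the
#'   event.
#' @param rate_hz Sampling rate.
#' @param theta_band Band edges for the theta filters (Hz).
#' @param spike_threshold_sd Inclusion threshold in SDs of the first
#'   second.
#' @param check_spike Set `FALSE` to bypass spike detection and truncate
#'   at `truncate_at` (sample index, default the segment end); used for
#'   validation on signals without a spike.
#' @param truncate_at Optional truncation sample when `check_spike` is
#'   `FALSE`.
#' @return List: `phase_rad` (or `NA`), `included`, `reason`,
#'   `onset_sample`.
#' @export
onset_phase <- function(segment, rate_hz, theta_band = c(4, 12),
                        spike_threshold_sd = 5, check_spike = TRUE,
                        truncate_at = NULL) {
  n <- length(segment)
  n1 <- min(round(rate_hz), n)              # first second
  base <- mean(segment[seq_len(n1)])
  s1 <- stats::sd(segment[seq_len(n1)])
  if (check_spike) {
    dev <- abs(segment - base)
    if (max(dev) < spike_threshold_sd * s1)
      return(list(phase_rad = NA_real_, included = FALSE,
                  reason = "subthreshold spike", onset_sample = NA_integer_))
    # spike peak: largest deviation in the final 300 ms
    tail_i <- max(1L, n - round(0.3 * rate_hz)):n
    pk <- tail_i[which.max(dev[tail_i])]
    # onset: walk back from the peak while the signal stays > 2 SD away
    on <- pk
    while (on > 1L && dev[on - 1L] > 2 * s1) on <- on - 1L
    onset <- on
  } else {
    onset <- if (is.null(truncate_at)) n else truncate_at
  }
  f_lo <- theta_band[1]
  min_n <- ceiling(6 / f_lo * rate_hz)
  if (onset < min_n)
    return(list(phase_rad = NA_real_, included = FALSE,
                reason = "fewer than six theta cycles", onset_sample = onset))
  x <- segment[seq_len(onset)] - base
  bf <- signal::butter(4, theta_band / (rate_hz / 2), type = "pass")
  zp <- signal::filtfilt(bf, x)
  cz <- as.numeric(signal::filter(bf, x))
  ph_zp <- Arg(analytic_signal(zp))
  ph_cz <- Arg(analytic_signal(cz))
  # offset between filters over the unperturbed interior
  i0 <- round(0.25 * rate_hz); i1 <- onset - round(0.25 * rate_hz)
  d <- ph_zp[i0:i1] - ph_cz[i0:i1]
  off <- Arg(mean(exp(1i * d)))              # circular mean
  # mean theta frequency from the causal phase slope over the interior
  inst_f <- diff(unwrap_phase(ph_cz[i0:i1])) * rate_hz / (2 * pi)
  f_hat <- stats::median(inst_f)
  if (!is.finite(f_hat) || f_hat <= 0) f_hat <- mean(theta_band)
  n6 <- min(onset - 1L, ceiling(6 / f_hat * rate_hz))
  idx <- (onset - n6):onset
  phi <- unwrap_phase(ph_cz[idx]) + off
  tt <- (idx - onset) / rate_hz
  fit <- stats::lm.fit(cbind(1, tt), phi)
  phase <- fit$coefficients[1]              # extrapolated to the onset
  list(phase_rad = wrap_phase(unname(phase)), included = TRUE,
       reason = NA_character_, onset_sample = onset)
}

unwrap_phase <- function(p) {
  d <- diff(p)
  d <- d - 2 * pi * round(d / (2 * pi))
  cumsum(c(p[1], d))
}

wrap_phase <- function(p) {
  ((p + pi) %% (2 * pi)) - pi
}

#' Peri-event theta and speed table for pHFO events
#'
#' For every pHFO occurring while the animal runs at or above the speed
#' threshold, extracts the 4 s radiatum segment, clips the interictal
#' spike, computes wavelet theta power in the baseline/before/after
#' windows, the running speed in the same windows, and the onset theta
#' phase. Events too close to the recording edges are excluded.
#'
#' @param lfp_rad Radiatum [lfp_signal()].
#' @param events Labelled events data frame (uses rows with
#'   `label == "pHFO"`, or all rows if no `label` column).
#' @param track Position track.
#' @param min_speed_cm_s Speed gate (cm/s).
#' @return Data frame: `event_id`, `power_bl`, `power_before`,
#'   `power_after`, `speed_bl`, `speed_before`, `speed_after`,
#'   `phase_rad`, `included`, `reason`.
#' @export
theta_around_events <- function(lfp_rad, events, track,
                                min_speed_cm_s = 5) {
  stopifnot(inherits(lfp_rad, "lfp_signal"))
  fs <- lfp_rad$rate_hz
  n <- length(lfp_rad$samples)
  sm <- mean(lfp_rad$samples)
  ev <- if ("label" %in% names(events))
    events[events$label == "pHFO", , drop = FALSE] else events
  sp <- stats::approx(track$time_s, track$speed_cm_s, ev$peak_time_s,
                      rule = 2)$y
  ev <- ev[sp >= min_speed_cm_s, , drop = FALSE]
  rows <- vector("list", nrow(ev))
  for (i in seq_len(nrow(ev))) {
    t0 <- ev$peak_time_s[i]
    c0 <- round(t0 * fs)
    if (c0 - 2 * fs < 1L || c0 + 2 * fs > n) next
    seg <- lfp_rad$samples[(c0 - 2 * fs + 1L):(c0 + 2 * fs)]
    seg <- clip_event_artifact(seg, sm, fs)
    pw <- theta_power_windows(morlet_power(seg, fs), fs)
    spd <- speed_windows(track, t0)
    pre <- lfp_rad$samples[(c0 - 2 * fs + 1L):c0]
    ph <- onset_phase(pre, fs)
    rows[[i]] <- data.frame(
      event_id = ev$event_id[i], power_bl = pw[["baseline"]],
      power_before = pw[["before"]], power_after = pw[["after"]],
      speed_bl = spd[["baseline"]], speed_before = spd[["before"]],
      speed_after = spd[["after"]], phase_rad = ph$phase_rad,
      included = ph$included,
      reason = if (is.na(ph$reason)) "" else ph$reason)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(event_id = integer(0), power_bl = numeric(0),
                      power_before = numeric(0), power_after = numeric(0),
                      speed_bl = numeric(0), speed_before = numeric(0),
                      speed_after = numeric(0), phase_rad = numeric(0),
                      included = logical(0), reason = character(0))
  out
}
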