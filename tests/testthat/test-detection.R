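fs <- 2000

test_that("ripple-band filter meets its design contract", {
  t <- seq(0, 2, by = 1 / fs)
  # DC is annihilated
  dc <- bandpass_ripple(rep(1, length(t)), fs)
  expect_lt(max(abs(dc[1000:3000])), 1e-3)
  # 300 Hz passes at unit gain within the passband ripple
  y300 <- bandpass_ripple(sin(2 * pi * 300 * t), fs)
  expect_lt(abs(max(y300[1500:2500]) - 1), 0.028 + 0.005)
  # 50 Hz is suppressed to the stopband ripple
  y50 <- bandpass_ripple(sin(2 * pi * 50 * t), fs)
  expect_lt(max(abs(y50[1500:2500])), 1e-3)
  # zero-lag: a 200 Hz burst keeps its temporal position
  x <- numeric(4001)
  idx <- 1900:2100
  x[idx] <- sin(2 * pi * 200 * (idx - 1900) / fs)
  y <- bandpass_ripple(x, fs)
  expect_lt(abs(which.max(abs(y)) - which.max(abs(x))), 15)
  expect_error(bandpass_ripple(numeric(10), fs), "shorter")
})

test_that("sliding RMS matches closed forms", {
  expect_equal(sliding_rms(rep(3, 100)), rep(3, 100))
  expect_equal(sliding_rms(rep(c(1, -1), 50)), rep(1, 100))
  # sinusoid with window >> period: A/sqrt(2) mid-signal
  t <- seq(0, 1, by = 1 / fs)
  r <- sliding_rms(2 * sin(2 * pi * 200 * t), window = 200)
  expect_lt(max(abs(r[500:1500] - 2 / sqrt(2))), 0.05)
  expect_error(sliding_rms(numeric(0)), "empty")
})

test_that("candidate detection merges runs within 6 ms but not beyond", {
  burst <- function(at_s, len_s = 0.02) {
    i <- round(at_s * fs):round((at_s + len_s) * fs)
    x <- numeric(2 * fs)
    x[i] <- sin(2 * pi * 200 * (i - i[1]) / fs)
    x
  }
  x <- 0.01 * sin(2 * pi * 300 * seq_len(2 * fs) / fs)  # tiny background
  one <- x + 10 * burst(0.5)
  iv <- detect_candidates(sliding_rms(bandpass_ripple(one, fs)), fs)
  expect_equal(nrow(iv), 1L)
  expect_true(iv[1, 1] <= 0.51 * fs && iv[1, 2] >= 0.5 * fs)
  # two bursts 4 ms apart merge; 10 ms apart stay separate
  close_pair <- x + 10 * (burst(0.5) + burst(0.524))
  iv2 <- detect_candidates(sliding_rms(bandpass_ripple(close_pair, fs)), fs)
  expect_equal(nrow(iv2), 1L)
  far_pair <- x + 10 * (burst(0.5) + burst(0.535))
  iv3 <- detect_candidates(sliding_rms(bandpass_ripple(far_pair, fs)), fs)
  expect_equal(nrow(iv3), 2L)
})

test_that("interval merging is idempotent", {
  iv <- cbind(start = c(10L, 30L, 100L), end = c(20L, 40L, 120L))
  m1 <- merge_intervals(iv, gap = 12L)
  expect_equal(nrow(m1), 2L)
  expect_identical(merge_intervals(m1, gap = 12L), m1)
})

test_that("cycle criterion keeps >=5-peak bursts and drops shorter ones", {
  mk <- function(n_cycles) {
    t <- seq_len(2 * fs) / fs
    x <- 0.1 * rnorm(2 * fs)
    dur <- n_cycles / 200
    i <- round(1 * fs):round((1 + dur) * fs)
    x[i] <- x[i] + 10 * sin(2 * pi * 200 * (i - i[1]) / fs)
    x
  }
  set.seed(9)
  x8 <- mk(8); x3 <- mk(3)
  iv <- cbind(start = round(0.99 * fs), end = round(1.06 * fs))
  expect_equal(nrow(cycle_criterion(x8, iv)), 1L)
  expect_equal(nrow(cycle_criterion(x3, iv)), 0L)
  # flat signal interval is dropped
  expect_equal(nrow(cycle_criterion(c(rnorm(fs), numeric(fs)),
                                    cbind(start = fs + 100L,
                                          end = fs + 500L))), 0L)
})

test_that("spectral validation separates ripples from fast gamma", {
  t <- seq_len(2 * fs) / fs
  mk <- function(f) {
    x <- 2 * rnorm(2 * fs)
    i <- round(1 * fs):round(1.04 * fs)
    x[i] <- x[i] + 50 * sin(2 * pi * f * (i - i[1]) / fs)
    x
  }
  set.seed(10)
  iv <- cbind(start = round(0.99 * fs), end = round(1.05 * fs))
  x186 <- mk(186)
  ev <- spectral_validation(x186, bandpass_ripple(x186, fs), iv, fs)
  expect_equal(nrow(ev), 1L)
  expect_lt(abs(ev$peak_freq_hz - 186), 10)
  x100 <- mk(100)
  expect_equal(nrow(spectral_validation(x100, bandpass_ripple(x100, fs),
                                        iv, fs)), 0L)
  # zero signal: rejected
  z <- numeric(2 * fs)
  expect_equal(nrow(spectral_validation(z, z, iv, fs)), 0L)
})

test_that("raising the RMS threshold never yields more events", {
  ses <- default_session()
  fs2 <- ses$lfp_pyr$rate_hz
  i <- seq_len(60 * fs2) + 300 * fs2          # one minute of foraging
  lfp <- lfp_signal(ses$lfp_pyr$samples[i], fs2, "pyramidale")
  n_ev <- vapply(c(2.5, 3.5, 5), function(thr)
    nrow(detect_hfo(lfp, params = detection_params(rms_threshold_sd = thr))),
    numeric(1))
  expect_true(all(diff(n_ev) <= 0))
})

test_that("detection recovers scheduled events and stays silent on noise", {
  ses <- default_session()
  ev <- default_events()
  hit <- vapply(ses$truth$time_s, function(t)
    any(abs(ev$peak_time_s - t) < 0.05), logical(1))
  expect_gte(mean(hit), 0.9)
  # false events: detections with no scheduled event within 100 ms
  fp <- vapply(ev$peak_time_s, function(t)
    all(abs(ses$truth$time_s - t) > 0.1), logical(1))
  expect_lte(sum(fp) / max(ses$epochs$end_s), 0.01)
  # pure-noise session yields (almost) nothing
  spec <- session_spec(epochs = data.frame(label = "forage",
                                           duration_s = 600),
                       ripple_rate_hz = 0, phfo_rate_hz = 0)
  noise <- simulate_session(spec, seed = 77L)
  nev <- detect_hfo(noise$lfp_pyr, noise$epochs)
  expect_lte(nrow(nev) / 600, 0.01)
})

test_that("amplitude CV arithmetic and session contrast behave", {
  expect_equal(amplitude_cv(rep(7, 25)), 0)
  amps <- c(rep(100, 20), rep(500, 20))
  expect_equal(amplitude_cv(amps), sd(amps) / mean(amps))
  expect_error(amplitude_cv(rep(1, 10)), "at least 20")
  # two-class session shows larger CV than a single-class session
  cv2 <- amplitude_cv(default_events())
  spec1 <- session_spec(phfo_rate_hz = 0)
  ses1 <- simulate_session(spec1, seed = 55L)
  cv1 <- amplitude_cv(detect_hfo(ses1$lfp_pyr, ses1$epochs))
  expect_lt(abs(cv1 - 0.3), 0.1)
  expect_lt(abs(cv2 - 0.5), 0.12)
  expect_gt(cv2, cv1)
})
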