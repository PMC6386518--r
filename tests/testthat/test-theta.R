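fs <- 2000

test_that("artifact clipping replaces exactly the centre window", {
  seg <- rnorm(4 * fs)
  out <- clip_event_artifact(seg, 0, fs)
  ctr <- length(seg) %/% 2
  expect_true(all(out[(ctr - 199):(ctr + 200)] == 0))
  expect_identical(out[1:(ctr - 200)], seg[1:(ctr - 200)])
  # a large central spike disappears
  seg2 <- rnorm(4 * fs)
  seg2[ctr] <- 1000
  out2 <- clip_event_artifact(seg2, 0, fs)
  expect_lt(max(abs(out2)), max(abs(seg2[-((ctr - 200):(ctr + 200))])) + 1e-9)
  expect_error(clip_event_artifact(numeric(fs), 0, fs), "4 s")
})

test_that("Morlet power localises frequency and tracks amplitude steps", {
  t <- seq_len(4 * fs) / fs
  expect_true(all(morlet_power(numeric(4 * fs), fs) == 0))
  P <- morlet_power(30 * sin(2 * pi * 9 * t), fs)
  f <- attr(P, "freqs")
  expect_lt(abs(f[which.max(P[, 2 * fs])] - 9), 0.5)
  # amplitude A sinusoid -> power ~ A^2 at its frequency
  expect_lt(abs(P[f == 9, 2 * fs] / 900 - 1), 0.05)
  # amplitude stepped to zero at t = 2 s
  x <- 30 * sin(2 * pi * 9 * t) * (t <= 2)
  pw <- theta_power_windows(morlet_power(x, fs), fs)
  expect_lt(pw[["after"]], 0.1 * pw[["before"]])
  # stationary signal: all three windows agree within 10%
  pst <- theta_power_windows(morlet_power(30 * sin(2 * pi * 9 * t), fs), fs)
  expect_lt(max(abs(pst / pst[["baseline"]] - 1)), 0.1)
})

test_that("power windows are translation equivariant", {
  # the same waveform analysed around two event positions in a longer
  # recording gives identical window powers
  tlong <- seq_len(10 * fs) / fs
  feature <- function(t0) 20 * sin(2 * pi * 8 * tlong) *
    exp(-((tlong - t0)^2))
  seg_at <- function(x, t0)
    x[(round(t0 * fs) - 2 * fs + 1):(round(t0 * fs) + 2 * fs)]
  p1 <- theta_power_windows(morlet_power(seg_at(feature(3), 3), fs), fs)
  p2 <- theta_power_windows(morlet_power(seg_at(feature(6), 6), fs), fs)
  expect_equal(p1, p2, tolerance = 0.02)
})

test_that("speed windows average the tracked speed per window", {
  tr <- data.frame(time_s = seq(0, 20, by = 1 / 30))
  tr$x_cm <- 10 * tr$time_s; tr$y_cm <- 0
  tr$speed_cm_s <- compute_speed(tr)
  sw <- speed_windows(tr, 10)
  expect_equal(unname(sw), c(10, 10, 10), tolerance = 0.05)
  # stopping after the event
  tr2 <- tr
  tr2$speed_cm_s[tr2$time_s > 10] <- 0
  sw2 <- speed_windows(tr2, 10)
  expect_lt(sw2[["after"]], sw2[["baseline"]])
})

test_that("onset phase is recovered across truncation phases", {
  phis <- seq(0, 2 * pi, length.out = 13)[-13]
  errs <- vapply(phis, function(phi0) {
    t <- seq_len(2 * fs) / fs
    x <- 100 * cos(2 * pi * 8 * t)
    k <- round((phi0 / (2 * pi * 8)) * fs) + round(1.6 * fs)
    r <- onset_phase(x[1:k], fs, check_spike = FALSE)
    circ_diff(r$phase_rad, ((2 * pi * 8 * k / fs + pi) %% (2 * pi)) - pi)
  }, numeric(1))
  expect_lt(max(errs), 0.3)
  # 20% additive noise: circular mean error < 0.5 rad over 100 trials
  set.seed(8)
  errn <- replicate(100, {
    t <- seq_len(2 * fs) / fs
    phi0 <- runif(1, 0, 2 * pi)
    x <- 100 * cos(2 * pi * 8 * t + phi0) + rnorm(2 * fs, 0, 20)
    r <- onset_phase(x, fs, check_spike = FALSE)
    tru <- ((2 * pi * 8 * 2 + phi0 + pi) %% (2 * pi)) - pi
    ((r$phase_rad - tru + pi) %% (2 * pi)) - pi
  })
  expect_lt(abs(Arg(mean(exp(1i * errn)))), 0.5)
})

test_that("sub-threshold interictal spikes are excluded", {
  t <- seq_len(2 * fs) / fs
  theta <- 50 * cos(2 * pi * 8 * t)
  spike <- function(mult) {
    x <- theta
    s1 <- sd(x[seq_len(fs)])
    i <- (2 * fs - 60):(2 * fs)
    x[i] <- mult * s1 * seq(0, 1, length.out = 61)^2  # spike replaces theta
    x
  }
  r4 <- onset_phase(spike(4), fs)
  expect_false(r4$included)
  expect_match(r4$reason, "subthreshold")
  r8 <- onset_phase(spike(8), fs)
  expect_true(r8$included)
  # too-short segments are excluded for lack of theta cycles
  rshort <- onset_phase(spike(8)[1:400], fs, check_spike = FALSE)
  expect_false(rshort$included)
})

test_that("causal/zero-phase offset is stable for narrowband signals", {
  t <- seq_len(2 * fs) / fs
  x <- 80 * cos(2 * pi * 8 * t) + rnorm(2 * fs, 0, 8)
  bf <- signal::butter(4, c(4, 12) / (fs / 2), type = "pass")
  zp <- signal::filtfilt(bf, x)
  cz <- as.numeric(signal::filter(bf, x))
  d <- Arg(ripplesift:::analytic_signal(zp)) -
    Arg(ripplesift:::analytic_signal(cz))
  d <- d[round(0.25 * fs):round(1.75 * fs)]
  z <- exp(1i * d)
  circ_sd <- sqrt(-2 * log(Mod(mean(z))))
  expect_lt(circ_sd, 0.3)
})

test_that("post-pHFO theta suppression is visible in the generator output", {
  spec <- session_spec(epochs = data.frame(label = "forage",
                                           duration_s = 120),
                       rad_noise_uV = 10)
  tr <- generate_trajectory(spec, seed = 9L)
  tru <- data.frame(time_s = c(30, 60, 90), class = "phfo", freq_hz = 246,
                    amp_uV = 200, env_uV = 520, speed_cm_s = 10)
  lfp <- synthesize_lfp(spec, tru, tr, seed = 9L)
  th <- theta_around_events(lfp$radiatum,
                            data.frame(event_id = 1:3,
                                       peak_time_s = tru$time_s),
                            tr, min_speed_cm_s = 0)
  expect_equal(nrow(th), 3L)
  expect_true(all(th$power_after < th$power_bl))
})
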