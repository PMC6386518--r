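test_that("generators are deterministic under a fixed seed", {
  spec <- session_spec(epochs = data.frame(label = c("rest", "forage"),
                                           duration_s = c(30, 60)),
                       n_units = 3)
  a <- simulate_session(spec, seed = 42L)
  b <- simulate_session(spec, seed = 42L)
  expect_identical(a$track, b$track)
  expect_identical(a$truth, b$truth)
  expect_identical(a$lfp_pyr$samples, b$lfp_pyr$samples)
  expect_identical(a$spikes, b$spikes)
  c <- simulate_session(spec, seed = 43L)
  expect_false(identical(a$truth, c$truth))
})

test_that("spec validation rejects invalid sessions", {
  expect_error(session_spec(epochs = data.frame(label = "forage",
                                                duration_s = -1)),
               "positive")
  expect_error(session_spec(lfp_rate_hz = 1000), "1620")
  expect_error(session_spec(ripple_rate_hz = -1), ">= 0")
  expect_error(generate_trajectory(
    session_spec(epochs = data.frame(label = "rest", duration_s = 60))),
    "foraging")
})

test_that("zero-speed spec pins the animal to one point", {
  spec <- session_spec(epochs = data.frame(label = "forage",
                                           duration_s = 60),
                       target_median_speed_cm_s = 0)
  tr <- generate_trajectory(spec, seed = 1L)
  expect_equal(diff(range(tr$x_cm)), 0)
  expect_equal(diff(range(tr$y_cm)), 0)
  expect_true(all(tr$speed_cm_s == 0))
})

test_that("default 10-min foraging covers >=95% of arena bins at target speed", {
  tr <- forage_track()
  ctx <- forage_context()
  nb <- ctx$nx * ctx$ny
  cx <- ctx$origin[1] + ((seq_len(nb) - 1) %% ctx$nx + 0.5) * ctx$bin_cm
  cy <- ctx$origin[2] + ((seq_len(nb) - 1) %/% ctx$nx + 0.5) * ctx$bin_cm
  inside <- sqrt((cx - 50)^2 + (cy - 50)^2) <= 50
  expect_gte(sum(ctx$visited & inside) / sum(inside), 0.95)
  # target median speed 6.4 cm/s realised within +-1 cm/s
  expect_lt(abs(median(tr$speed_cm_s) - 6.4), 1)
})

test_that("event scheduling respects class-specific brain-state rules", {
  spec <- session_spec()
  tr <- generate_trajectory(spec, seed = 2L)
  tru <- schedule_events(spec, tr, seed = 2L)
  # ripples only at sub-threshold speeds
  expect_lt(max(tru$speed_cm_s[tru$class == "ripple"]), 5)
  # pHFO rate 0 leaves only the ripple class
  spec0 <- session_spec(phfo_rate_hz = 0)
  tru0 <- schedule_events(spec0, tr, seed = 2L)
  expect_setequal(unique(tru0$class), "ripple")
  # minimum gap enforced
  expect_true(all(diff(tru$time_s) >= spec$min_gap_s))
  # infeasible rates error out
  expect_error(schedule_events(session_spec(phfo_rate_hz = 2), tr),
               "infeasible")
})

test_that("pHFO counts are Poisson-consistent and state independent", {
  spec <- session_spec(epochs = data.frame(label = "forage",
                                           duration_s = 600),
                       ripple_rate_hz = 0, phfo_rate_hz = 0.1)
  tr <- generate_trajectory(spec, seed = 4L)
  counts <- vapply(1:8, function(s)
    nrow(schedule_events(spec, tr, seed = s)), numeric(1))
  # 95% Poisson interval for lambda = 60 (598 usable seconds), allowing
  # for the small loss from gap enforcement
  expect_true(all(counts > qpois(0.025, 60) - 5 & counts < qpois(0.975, 60)))
  # speed at pHFOs indistinguishable from the occupancy speed distribution
  tru <- do.call(rbind, lapply(1:4, function(s)
    schedule_events(spec, tr, seed = 100 + s)))
  p <- wilcox.test(tru$speed_cm_s,
                   sample(tr$speed_cm_s, 2000))$p.value
  expect_gt(p, 0.01)
})

test_that("synthesized LFP carries the scheduled waveforms", {
  spec <- session_spec(epochs = data.frame(label = "forage",
                                           duration_s = 30),
                       pyr_noise_uV = 0, rad_noise_uV = 0,
                       theta_amp_uV = 0)
  tr <- generate_trajectory(spec, seed = 1L)
  # no events, zero noise -> silent pyramidal trace
  lfp0 <- synthesize_lfp(spec, no_events(), tr, seed = 1L)
  expect_equal(max(abs(lfp0$pyramidale$samples)), 0)
  # one ripple at t = 10 s: spectral peak within 186 +- 5 Hz
  tru <- data.frame(time_s = 10, class = "ripple", freq_hz = 186,
                    amp_uV = 100, env_uV = 0.001, speed_cm_s = 0)
  lfp1 <- synthesize_lfp(spec, tru, tr, seed = 1L)
  fs <- spec$lfp_rate_hz
  seg <- lfp1$pyramidale$samples[(10 * fs - 100):(10 * fs + 100)]
  n <- length(seg)
  pw <- Mod(fft(seg - mean(seg)))[1:(n %/% 2)]^2
  fgrid <- (seq_len(n %/% 2) - 1) * fs / n
  expect_lt(abs(fgrid[which.max(pw)] - 186), 5)
  # events lying outside the session are rejected
  expect_error(synthesize_lfp(spec, transform(tru, time_s = 99), tr),
               "inside the session")
})

test_that("scheduled envelope amplitudes are recovered by the classifier", {
  # pHFO envelope set to 520 uV must be extracted as ~520 uV +- 10%
  spec <- session_spec(epochs = data.frame(label = "forage",
                                           duration_s = 60),
                       pyr_noise_uV = 0, theta_amp_uV = 0)
  tr <- generate_trajectory(spec, seed = 1L)
  tru <- data.frame(time_s = c(15, 30, 45),
                    class = c("phfo", "phfo", "ripple"),
                    freq_hz = c(246, 246, 186), amp_uV = c(200, 200, 100),
                    env_uV = c(520, 520, 244.9), speed_cm_s = 0)
  lfp <- synthesize_lfp(spec, tru, tr, seed = 1L)
  ev <- data.frame(event_id = 1:3, peak_time_s = tru$time_s)
  fe <- extract_features(lfp$pyramidale, ev)
  expect_lt(max(abs(fe$envelope_uV[1:2] - 520) / 520), 0.10)
  expect_lt(abs(fe$envelope_uV[3] - 244.9) / 244.9, 0.10)
})

test_that("spike synthesis follows place fields and event gains", {
  spec <- session_spec(epochs = data.frame(label = "forage",
                                           duration_s = 600),
                       n_units = 1, baseline_rate_hz = 2,
                       peak_rate_hz = 0, mod_fractions =
                         c(ripple = 1, phfo = 0, both = 0))
  tr <- generate_trajectory(spec, seed = 5L)
  # peak rate 0 and baseline 0 -> empty train
  spec0 <- session_spec(epochs = spec$epochs, n_units = 1,
                        baseline_rate_hz = 0, peak_rate_hz = 0)
  sp0 <- synthesize_spikes(spec0, no_events(), tr, seed = 1L)
  expect_equal(nrow(sp0$spikes), 0)
  # gain 5 on 50 ripple events makes the unit detectably modulated
  ev <- data.frame(time_s = seq(5, 595, length.out = 50), class = "ripple",
                   freq_hz = 186, amp_uV = 100, env_uV = 245,
                   speed_cm_s = 0)
  sp <- synthesize_spikes(spec, ev, tr, seed = 6L)
  expect_true(sp$units$mod_ripple[1])
  res <- modulation_test(peri_event_rates(sp$spikes$time_s, ev$time_s))
  expect_lt(res$p_value, 0.05)
  expect_gt(res$rate_event_hz, res$rate_bl_hz)
  # gain 1 (no modulation): event-window counts match the baseline rate
  specg1 <- session_spec(epochs = spec$epochs, n_units = 1,
                         baseline_rate_hz = 2, peak_rate_hz = 0,
                         mod_fractions = c(ripple = 0, phfo = 0, both = 0))
  sp1 <- synthesize_spikes(specg1, ev, tr, seed = 7L)
  res1 <- modulation_test(peri_event_rates(sp1$spikes$time_s, ev$time_s))
  expect_gt(res1$p_value, 0.05)
})
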