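#' Specification of a synthetic recording session
#'
#' Describes one session of the kind the analysis pipeline expects:
#' alternating rest and foraging epochs, a pyramidal-layer and a stratum
#' radiatum LFP channel, sorted single units with place fields, and two
#' classes of high-frequency events. Class waveform parameters default to
#' the feature medians measured in chronically epileptic and control rats:
#' ripples/ripple-like events oscillate near 186 Hz on ~245 uV sharp-wave
#' envelopes and occur only during immobility, while pHFOs oscillate near
#' 246 Hz on ~520 uV interictal-spike envelopes and occur at all running
#' speeds. Envelope amplitudes are in measured units: the generator scales
#' each injected transient so that the classifier's 0.2-40 Hz envelope
#' feature recovers the nominal value.
#'
#' @param epochs Data frame with columns `label` ("rest"/"forage") and
#'   `duration_s`. Default: 300 s rest, 600 s forage, 300 s rest.
#' @param lfp_rate_hz LFP sampling rate (Hz).
#' @param tracking_rate_hz Position sampling rate (Hz).
#' @param arena `"circle"` (diameter `arena_cm`) or `"square"` (side).
#' @param arena_cm Arena size in cm.
#' @param classes Named list of event-class parameter lists; see Details.
#' @param ripple_rate_hz Ripple event rate per second of immobility.
#' @param phfo_rate_hz pHFO rate per second of session (state independent).
#' @param min_gap_s Minimum gap between scheduled events.
#' @param immobility_cm_s Speed below which ripples may be scheduled.
#' @param target_median_speed_cm_s Target median running speed while
#'   foraging.
#' @param n_units Number of simulated single units.
#' @param field_width_cm Place-field Gaussian SD.
#' @param peak_rate_hz In-field peak rate added to baseline.
#' @param baseline_rate_hz Out-of-field rate.
#' @param silent_fraction Fraction of units with no place field.
#' @param mod_gain Rate multiplier during the 100 ms core of events a unit
#'   is modulated by.
#' @param mod_fractions Named numeric: fractions of units modulated by
#'   ripple only, pHFO only, and both.
#' @param pyr_noise_uV SD of Gaussian noise on the pyramidal channel.
#' @param rad_noise_uV SD of Gaussian noise on the radiatum channel.
#' @param theta_freq_hz,theta_amp_uV Theta oscillation parameters.
#' @param theta_suppression Depth (0-1) of post-pHFO theta suppression.
#' @param theta_suppression_window_s Start/end of the suppression window
#'   relative to the pHFO.
#' @return Object of class `session_spec`.
#' @details Each class parameter list has entries `freq_hz`, `freq_sd_hz`,
#'   `n_cycles`, `amp_uV` (median peak amplitude of the band-passed
#'   oscillation), `amp_cv`, `env_uV` (median envelope amplitude),
#'   `env_sdlog` (log-normal spread), and `shape` ("sharp_wave" or
#'   "interictal_spike").
#' @export
session_spec <- function(epochs = data.frame(
                           label = c("rest", "forage", "rest"),
                           duration_s = c(300, 600, 300)),
                         lfp_rate_hz = 2000, tracking_rate_hz = 30,
                         arena = c("circle", "square"), arena_cm = 100,
                         classes = default_event_classes(),
                         ripple_rate_hz = 0.3, phfo_rate_hz = 0.1,
                         min_gap_s = 0.5, immobility_cm_s = 5,
                         target_median_speed_cm_s = 6.4,
                         n_units = 30, field_width_cm = 10,
                         peak_rate_hz = 5, baseline_rate_hz = 0.2,
                         silent_fraction = 0, mod_gain = 5,
                         mod_fractions = c(ripple = 0.6, phfo = 0.12,
                                           both = 0.28),
                         pyr_noise_uV = 12, rad_noise_uV = 30,
                         theta_freq_hz = 8, theta_amp_uV = 150,
                         theta_suppression = 0.8,
                         theta_suppression_window_s = c(0.1, 0.8)) {
  arena <- match.arg(arena)
  spec <- list(epochs = epochs, lfp_rate_hz = lfp_rate_hz,
               tracking_rate_hz = tracking_rate_hz, arena = arena,
               arena_cm = arena_cm, classes = classes,
               ripple_rate_hz = ripple_rate_hz, phfo_rate_hz = phfo_rate_hz,
               min_gap_s = min_gap_s, immobility_cm_s = immobility_cm_s,
               target_median_speed_cm_s = target_median_speed_cm_s,
               n_units = n_units, field_width_cm = field_width_cm,
               peak_rate_hz = peak_rate_hz, baseline_rate_hz = baseline_rate_hz,
               silent_fraction = silent_fraction, mod_gain = mod_gain,
               mod_fractions = mod_fractions, pyr_noise_uV = pyr_noise_uV,
               rad_noise_uV = rad_noise_uV, theta_freq_hz = theta_freq_hz,
               theta_amp_uV = theta_amp_uV,
               theta_suppression = theta_suppression,
               theta_suppression_window_s = theta_suppression_window_s)
  class(spec) <- "session_spec"
  validate_session_spec(spec)
  spec
}

#' @rdname session_spec
#' @export
default_event_classes <- function() {
  list(
    ripple = list(freq_hz = 185.8, freq_sd_hz = 8.15, n_cycles = 12,
                  amp_uV = 130, amp_cv = 0.3,
                  env_uV = 244.9, env_sdlog = 0.299, shape = "sharp_wave"),
    phfo = list(freq_hz = 245.9, freq_sd_hz = 11.25, n_cycles = 12,
                amp_uV = 260, amp_cv = 0.3,
                env_uV = 520.0, env_sdlog = 0.172, shape = "interictal_spike"))
}

validate_session_spec <- function(spec) {
  with(spec, {
    if (any(epochs$duration_s <= 0)) stop("epoch durations must be positive")
    if (!all(epochs$label %in% c("rest", "forage")))
      stop("epoch labels must be 'rest' or 'forage'")
    if (lfp_rate_hz <= 2 * 810) stop("lfp_rate_hz must exceed 1620 Hz")
    if (arena_cm <= 0) stop("arena size must be positive")
    if (ripple_rate_hz < 0 || phfo_rate_hz < 0) stop("rates must be >= 0")
    if (target_median_speed_cm_s < 0) stop("target speed must be >= 0")
    if (baseline_rate_hz < 0 || peak_rate_hz < 0) stop("rates must be >= 0")
    for (cl in classes)
      if (cl$freq_hz <= 150 || cl$freq_hz > 600)
        stop("class oscillation frequency must lie in (150, 600] Hz")
  })
  invisible(spec)
}

epoch_table <- function(spec) {
  e <- spec$epochs
  e$end_s <- cumsum(e$duration_s)
  e$start_s <- e$end_s - e$duration_s
  e[, c("label", "start_s", "end_s")]
}

# evaluate expr with a temporary RNG seed, restoring global state after
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generate a random-foraging trajectory
#'
#' Foraging epochs emulate a rat searching for randomly scattered food:
#' an Ornstein-Uhlenbeck velocity process (0.7 s correlation time) whose
#' mean is steered towards a sequence of waypoints drawn preferentially
#' from not-yet-visited 5 cm bins, reflected at the arena walls. The
#' waypoint mechanism reproduces the near-complete arena coverage of real
#' foraging within a 10 min epoch; the velocity scale is set so the
#' realised median running speed (as measured by [compute_speed()])
#' matches the spec's target. During rest epochs the animal sits in a
#' 20 x 20 cm holding box beside the arena with small residual movement.
#'
#' @param spec A [session_spec()].
#' @param seed Integer seed.
#' @return Data frame of class `position_track` with columns `time_s`,
#'   `x_cm`, `y_cm`, `epoch`, `speed_cm_s`.
#' @export
generate_trajectory <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "session_spec"))
  ep <- epoch_table(spec)
  if (!any(ep$label == "forage" & ep$end_s > ep$start_s))
    stop("at least one foraging epoch with positive duration is required")
  dt <- 1 / spec$tracking_rate_hz
  # cruise/jitter scales calibrated against the 250 ms speed smoothing
  beta <- spec$target_median_speed_cm_s * 0.97
  sigma <- spec$target_median_speed_cm_s * 0.625
  with_seed(seed, {
    out <- vector("list", nrow(ep))
    size <- spec$arena_cm
    start_xy <- c(size / 2, size / 2)
    box <- c(-30, -10, size / 2 - 10, size / 2 + 10)  # x0 x1 y0 y1
    for (i in seq_len(nrow(ep))) {
      n <- round((ep$end_s[i] - ep$start_s[i]) / dt)
      tt <- ep$start_s[i] + (seq_len(n) - 1L) * dt
      if (ep$label[i] == "forage") {
        p <- forage_path(n, dt, tau = 0.7, sigma = sigma, beta = beta,
                         start = start_xy, arena = spec$arena, size = size)
        start_xy <- p[n, ]
      } else {
        bc <- c(mean(box[1:2]), mean(box[3:4]))
        still <- spec$target_median_speed_cm_s <= 0
        p <- forage_path(n, dt, tau = 0.7, sigma = if (still) 0 else 0.4,
                         beta = if (still) 0 else 0.3,
                         start = bc, arena = "square", size = 20,
                         origin = c(box[1], box[3]))
      }
      out[[i]] <- data.frame(time_s = tt, x_cm = p[, 1], y_cm = p[, 2],
                             epoch = i)
    }
    track <- do.call(rbind, out)
    track$speed_cm_s <- compute_speed(track)
    class(track) <- c("position_track", "data.frame")
    track
  })
}

# waypoint-steered OU velocity walk reflected at walls; arena "circle"
# is the inscribed circle of the [origin, origin + size] box
forage_path <- function(n, dt, tau, sigma, beta, start, arena = "square",
                        size = 100, origin = c(0, 0), gb = 5) {
  a <- exp(-dt / tau)
  b <- sigma * sqrt(1 - a^2)
  p <- matrix(0, n, 2)
  p[1, ] <- start
  v <- c(0, 0)
  ctr <- origin + size / 2
  r <- size / 2
  if (beta <= 0 && sigma <= 0) {            # immobile spec
    p[] <- rep(start, each = n)
    return(p)
  }
  ng <- max(1L, ceiling(size / gb))
  gx <- origin[1] + (rep(seq_len(ng), ng) - 0.5) * gb
  gy <- origin[2] + (rep(seq_len(ng), each = ng) - 0.5) * gb
  rad <- sqrt((gx - ctr[1])^2 + (gy - ctr[2])^2)
  ok <- if (arena == "circle") rad <= r else rep(TRUE, ng * ng)
  # approach point: bin centre pulled just inside the wall
  if (arena == "circle") {
    sc <- pmin(1, (r - 1.5) / pmax(rad, 1e-9))
    ax <- ctr[1] + (gx - ctr[1]) * sc
    ay <- ctr[2] + (gy - ctr[2]) * sc
  } else {
    ax <- pmin(pmax(gx, origin[1] + 1.5), origin[1] + size - 1.5)
    ay <- pmin(pmax(gy, origin[2] + 1.5), origin[2] + size - 1.5)
  }
  occ <- numeric(ng * ng)
  pick <- function(pos) {
    unv <- ok & occ < 0.2
    w <- if (any(unv))
      ifelse(unv, exp(-sqrt((gx - pos[1])^2 + (gy - pos[2])^2) / 25), 0)
    else ifelse(ok, 1, 0)
    sample.int(ng * ng, 1, prob = w)
  }
  g <- pick(start)
  goal <- c(ax[g], ay[g])
  for (i in seq_len(n - 1L)) {
    bi <- pmin(pmax(floor((p[i, 1] - origin[1]) / gb), 0), ng - 1L) +
      ng * pmin(pmax(floor((p[i, 2] - origin[2]) / gb), 0), ng - 1L) + 1L
    occ[bi] <- occ[bi] + dt
    d <- goal - p[i, ]
    dn <- sqrt(sum(d^2))
    if (dn < 2.2 || occ[g] >= 0.25) {
      g <- pick(p[i, ])
      goal <- c(ax[g], ay[g])
      d <- goal - p[i, ]
      dn <- sqrt(sum(d^2))
    }
    mu <- beta * d / max(dn, 1e-9)
    v <- mu + a * (v - mu) + b * stats::rnorm(2)
    q <- p[i, ] + v * dt
    if (arena == "circle") {
      dd <- q - ctr
      ddn <- sqrt(sum(dd^2))
      if (ddn > r) {
        u <- dd / ddn
        q <- ctr + u * (2 * r - ddn)         # reflect across the wall
        v <- v - 2 * sum(v * u) * u
      }
    } else {
      for (k in 1:2) {
        lo <- origin[k]; hi <- origin[k] + size
        if (q[k] < lo) { q[k] <- 2 * lo - q[k]; v[k] <- -v[k] }
        if (q[k] > hi) { q[k] <- 2 * hi - q[k]; v[k] <- -v[k] }
      }
    }
    p[i + 1L, ] <- q
  }
  p
}

#' Schedule ground-truth high-frequency events
#'
#' Ripple-class events are drawn as a Poisson process over the time the
#' animal is immobile (speed below the immobility threshold, which
#' includes rest epochs), mirroring the brain-state dependence of normal
#' ripples. pHFO-class events are a homogeneous Poisson process over the
#' whole session, independent of running speed. A minimum inter-event gap
#' is enforced and events within 1 s of an epoch boundary are not
#' scheduled, so every event supports the detection and classification
#' analysis windows.
#'
#' @param spec A [session_spec()].
#' @param track Trajectory from [generate_trajectory()].
#' @param seed Integer seed.
#' @return Data frame of class `ground_truth`: `time_s`, `class`,
#'   `freq_hz`, `amp_uV`, `env_uV`, `speed_cm_s`.
#' @export
schedule_events <- function(spec, track, seed = 1L) {
  stopifnot(inherits(spec, "session_spec"))
  ep <- epoch_table(spec)
  total_s <- max(ep$end_s)
  dt <- 1 / spec$tracking_rate_hz
  if ((spec$ripple_rate_hz + spec$phfo_rate_hz) * spec$min_gap_s > 0.8)
    stop("event rates are infeasible under the minimum-gap constraint")
  with_seed(seed, {
    margin_ok <- rep(FALSE, nrow(track))
    for (i in seq_len(nrow(ep)))
      margin_ok <- margin_ok | (track$time_s >= ep$start_s[i] + 1 &
                                track$time_s <= ep$end_s[i] - 1)
    imm <- margin_ok & track$speed_cm_s < spec$immobility_cm_s
    n_rip <- stats::rpois(1, spec$ripple_rate_hz * sum(imm) * dt)
    t_rip <- if (n_rip > 0 && any(imm))
      sort(sample(track$time_s[imm], min(n_rip, sum(imm)))) else numeric(0)
    n_ph <- stats::rpois(1, spec$phfo_rate_hz * total_s)
    t_ph <- if (n_ph > 0)
      sort(stats::runif(n_ph, 0, total_s)) else numeric(0)
    # keep pHFOs clear of epoch boundaries too
    if (length(t_ph)) {
      ok <- vapply(t_ph, function(t0)
        any(t0 >= ep$start_s + 1 & t0 <= ep$end_s - 1), logical(1))
      t_ph <- t_ph[ok]
    }
    ev <- data.frame(time_s = c(t_rip, t_ph),
                     class = c(rep("ripple", length(t_rip)),
                               rep("phfo", length(t_ph))))
    ev <- ev[order(ev$time_s), , drop = FALSE]
    # greedy minimum-gap enforcement: keep the earlier event of any pair
    if (nrow(ev) > 1) {
      keep <- rep(TRUE, nrow(ev))
      last <- -Inf
      for (i in seq_len(nrow(ev))) {
        if (ev$time_s[i] - last < spec$min_gap_s) keep[i] <- FALSE
        else last <- ev$time_s[i]
      }
      ev <- ev[keep, , drop = FALSE]
    }
    ev$freq_hz <- rep(NA_real_, nrow(ev))
    ev$amp_uV <- rep(NA_real_, nrow(ev))
    ev$env_uV <- rep(NA_real_, nrow(ev))
    for (cl in names(spec$classes)) {
      idx <- which(ev$class == cl)
      if (!length(idx)) next
      p <- spec$classes[[cl]]
      f <- stats::rnorm(length(idx), p$freq_hz, p$freq_sd_hz)
      ev$freq_hz[idx] <- pmin(pmax(f, 155), 595)
      sdlog_a <- sqrt(log(1 + p$amp_cv^2))
      ev$amp_uV[idx] <- stats::rlnorm(length(idx), log(p$amp_uV), sdlog_a)
      ev$env_uV[idx] <- stats::rlnorm(length(idx), log(p$env_uV), p$env_sdlog)
    }
    ev$speed_cm_s <- stats::approx(track$time_s, track$speed_cm_s,
                                   ev$time_s, rule = 2)$y
    rownames(ev) <- NULL
    class(ev) <- c("ground_truth", "data.frame")
    ev
  })
}

# template transient shapes, peak amplitude 1 at the event time origin
transient_shape <- function(shape, t) {
  switch(shape,
         sharp_wave = -exp(-t^2 / (2 * 0.04^2)),
         interictal_spike = {
           w <- 0.025
           -(t / w) * exp(0.5 - t^2 / (2 * w^2))
         },
         stop("unknown transient shape: ", shape))
}

# peak of the 0.2-40 Hz filtered unit template, used to express envelope
# amplitudes in measured units
envelope_calibration <- function(shape, rate_hz) {
  t <- seq(-0.25, 0.25, by = 1 / rate_hz)
  x <- transient_shape(shape, t)
  max(abs(signal::filtfilt(slow_envelope_filter(rate_hz), x)))
}

#' Synthesize the pyramidal-layer and radiatum LFP channels
#'
#' The pyramidal channel is Gaussian noise plus, for each scheduled event,
#' a Hann-windowed sinusoid at the event's oscillation frequency riding on
#' a slow envelope transient: a negative Gaussian bump (40 ms SD) for
#' sharp-wave events and a biphasic derivative-of-Gaussian deflection for
#' interictal spikes. The radiatum channel carries a theta oscillation
#' whose amplitude is gated by running speed, the interictal-spike
#' transient of each pHFO (shared across layers), and a transient
#' suppression of theta after each pHFO. Envelope transients are scaled so
#' the classifier's 0.2-40 Hz envelope feature recovers the scheduled
#' `env_uV`.
#'
#' @param spec A [session_spec()].
#' @param truth Events from [schedule_events()].
#' @param track Trajectory from [generate_trajectory()].
#' @param seed Integer seed.
#' @return List with elements `pyramidale` and `radiatum`, each an
#'   [lfp_signal()].
#' @export
synthesize_lfp <- function(spec, truth, track, seed = 1L) {
  stopifnot(inherits(spec, "session_spec"))
  fs <- spec$lfp_rate_hz
  total_s <- max(epoch_table(spec)$end_s)
  n <- round(total_s * fs)
  tgrid_dt <- 1 / fs
  if (nrow(truth) && (min(truth$time_s) < 0 || max(truth$time_s) > total_s))
    stop("ground-truth events must lie inside the session")
  cal <- vapply(c(sharp_wave = "sharp_wave",
                  interictal_spike = "interictal_spike"),
                envelope_calibration, numeric(1), rate_hz = fs)
  with_seed(seed, {
    pyr <- if (spec$pyr_noise_uV > 0)
      stats::rnorm(n, 0, spec$pyr_noise_uV) else numeric(n)
    rad <- if (spec$rad_noise_uV > 0)
      stats::rnorm(n, 0, spec$rad_noise_uV) else numeric(n)
    # theta gated by speed (smoothly via the tracked speed series)
    if (spec$theta_amp_uV > 0) {
      tl <- (seq_len(n) - 1L) * tgrid_dt
      sp <- stats::approx(track$time_s, track$speed_cm_s, tl, rule = 2)$y
      gate <- sp / (sp + 2)
      supp <- rep(1, n)
      if (nrow(truth)) for (t0 in truth$time_s[truth$class == "phfo"]) {
        i0 <- max(1L, ceiling((t0 + spec$theta_suppression_window_s[1]) * fs))
        i1 <- min(n, floor((t0 + spec$theta_suppression_window_s[2]) * fs))
        if (i1 >= i0) supp[i0:i1] <- supp[i0:i1] * (1 - spec$theta_suppression)
      }
      rad <- rad + spec$theta_amp_uV * gate * supp *
        sin(2 * pi * spec$theta_freq_hz * tl)
    }
    if (nrow(truth)) for (i in seq_len(nrow(truth))) {
      p <- spec$classes[[truth$class[i]]]
      t0 <- truth$time_s[i]
      # oscillation burst
      half <- p$n_cycles / truth$freq_hz[i] / 2
      i0 <- max(1L, ceiling((t0 - half) * fs)); i1 <- min(n, floor((t0 + half) * fs))
      tt <- (i0:i1 - 1L) * tgrid_dt - t0
      win <- 0.5 * (1 + cos(pi * tt / half))
      pyr[i0:i1] <- pyr[i0:i1] +
        truth$amp_uV[i] * win * sin(2 * pi * truth$freq_hz[i] * tt)
      # slow envelope transient
      j0 <- max(1L, ceiling((t0 - 0.15) * fs)); j1 <- min(n, floor((t0 + 0.15) * fs))
      ts <- (j0:j1 - 1L) * tgrid_dt - t0
      tr <- transient_shape(p$shape, ts) * truth$env_uV[i] / cal[[p$shape]]
      pyr[j0:j1] <- pyr[j0:j1] + tr
      if (p$shape == "interictal_spike") rad[j0:j1] <- rad[j0:j1] + tr
    }
    list(pyramidale = lfp_signal(pyr, fs, "pyramidale"),
         radiatum = lfp_signal(rad, fs, "radiatum"))
  })
}

#' Synthesize place-field spike trains
#'
#' Each unit is an inhomogeneous Poisson process with rate equal to a
#' baseline plus a Gaussian place field evaluated at the animal's
#' position; during the 100 ms core of each event of a class the unit is
#' modulated by, the rate is multiplied by the unit's gain for that class.
#' Units are generated by thinning. Ground-truth modulation flags and
#' field parameters are returned alongside the spikes.
#'
#' @param spec A [session_spec()].
#' @param truth Events from [schedule_events()].
#' @param track Trajectory from [generate_trajectory()].
#' @param seed Integer seed.
#' @return List with `units` (data frame of per-unit ground truth) and
#'   `spikes` (data frame `unit_id`, `time_s`).
#' @export
synthesize_spikes <- function(spec, truth, track, seed = 1L) {
  stopifnot(inherits(spec, "session_spec"))
  total_s <- max(epoch_table(spec)$end_s)
  with_seed(seed, {
    nu <- spec$n_units
    size <- spec$arena_cm
    # field centres uniform over the arena interior
    if (spec$arena == "circle") {
      th <- stats::runif(nu, 0, 2 * pi)
      rr <- (size / 2 - 10) * sqrt(stats::runif(nu))
      fx <- size / 2 + rr * cos(th); fy <- size / 2 + rr * sin(th)
    } else {
      fx <- stats::runif(nu, 10, size - 10); fy <- stats::runif(nu, 10, size - 10)
    }
    silent <- stats::runif(nu) < spec$silent_fraction
    mf <- spec$mod_fractions
    cat_draw <- sample(c("ripple", "phfo", "both", "none"), nu, replace = TRUE,
                       prob = c(mf[["ripple"]], mf[["phfo"]], mf[["both"]],
                                max(0, 1 - sum(mf))))
    units <- data.frame(unit_id = seq_len(nu), field_x_cm = fx,
                        field_y_cm = fy,
                        field_width_cm = spec$field_width_cm,
                        peak_hz = ifelse(silent, 0, spec$peak_rate_hz),
                        baseline_hz = spec$baseline_rate_hz,
                        gain_ripple = ifelse(cat_draw %in% c("ripple", "both"),
                                             spec$mod_gain, 1),
                        gain_phfo = ifelse(cat_draw %in% c("phfo", "both"),
                                           spec$mod_gain, 1))
    units$mod_ripple <- units$gain_ripple > 1
    units$mod_phfo <- units$gain_phfo > 1
    ev_rip <- truth$time_s[truth$class == "ripple"]
    ev_ph <- truth$time_s[truth$class == "phfo"]
    spikes <- vector("list", nu)
    for (u in seq_len(nu)) {
      lam_max <- (units$baseline_hz[u] + units$peak_hz[u]) *
        max(units$gain_ripple[u], units$gain_phfo[u])
      if (lam_max <= 0) { spikes[[u]] <- numeric(0); next }
      ncand <- stats::rpois(1, lam_max * total_s)
      tc <- sort(stats::runif(ncand, 0, total_s))
      px <- stats::approx(track$time_s, track$x_cm, tc, rule = 2)$y
      py <- stats::approx(track$time_s, track$y_cm, tc, rule = 2)$y
      d2 <- (px - fx[u])^2 + (py - fy[u])^2
      lam <- units$baseline_hz[u] +
        units$peak_hz[u] * exp(-d2 / (2 * spec$field_width_cm^2))
      g <- rep(1, ncand)
      if (units$gain_ripple[u] > 1 && length(ev_rip))
        g[in_event_core(tc, ev_rip)] <- units$gain_ripple[u]
      if (units$gain_phfo[u] > 1 && length(ev_ph))
        g[in_event_core(tc, ev_ph)] <- units$gain_phfo[u]
      keep <- stats::runif(ncand) < lam * g / lam_max
      spikes[[u]] <- tc[keep]
    }
    sp <- data.frame(
      unit_id = rep(seq_len(nu), lengths(spikes)),
      time_s = unlist(spikes))
    list(units = units, spikes = sp)
  })
}

# TRUE for times within the 100 ms core of any event
in_event_core <- function(times, event_times, half_s = 0.05) {
  if (!length(event_times)) return(rep(FALSE, length(times)))
  ev <- sort(event_times)
  i <- findInterval(times, ev)
  near_lo <- i >= 1 & abs(times - ev[pmax(i, 1)]) <= half_s
  near_hi <- i < length(ev) & abs(ev[pmin(i + 1L, length(ev))] - times) <= half_s
  near_lo | near_hi
}

#' Simulate a complete session
#'
#' Runs trajectory generation, event scheduling, LFP synthesis and spike
#' synthesis with sub-seeds derived from one master seed, and returns all
#' components plus ground truth.
#'
#' @param spec A [session_spec()].
#' @param seed Integer master seed (< 2^20; sub-seeds stay below 2^31).
#' @return Object of class `hfo_session`: list with `spec`, `epochs`,
#'   `track`, `lfp_pyr`, `lfp_rad`, `units`, `spikes`, `truth`, `seed`.
#' @export
simulate_session <- function(spec = session_spec(), seed = 1L) {
  seed <- as.integer(seed)
  track <- generate_trajectory(spec, seed = seed * 1000L + 1L)
  truth <- schedule_events(spec, track, seed = seed * 1000L + 2L)
  lfp <- synthesize_lfp(spec, truth, track, seed = seed * 1000L + 3L)
  sp <- synthesize_spikes(spec, truth, track, seed = seed * 1000L + 4L)
  structure(list(spec = spec, epochs = epoch_table(spec), track = track,
                 lfp_pyr = lfp$pyramidale, lfp_rad = lfp$radiatum,
                 units = sp$units, spikes = sp$spikes, truth = truth,
                 seed = seed),
            class = "hfo_session")
}

#' @export
print.hfo_session <- function(x, ...) {
  cat(sprintf(
    "hfo_session: %.0f s, %d epochs, %d units, %d scheduled events (%s)\n",
    max(x$epochs$end_s), nrow(x$epochs), nrow(x$units), nrow(x$truth),
    paste(sprintf("%s=%d", names(table(x$truth$class)),
                  as.integer(table(x$truth$class))), collapse = ", ")))
  invisible(x)
}
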