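#' Run the full analysis pipeline on one session
#'
#' Orchestrates every stage on a session: event detection, feature
#' extraction and classification against a control reference, theta/speed
#' dynamics around pHFOs, unit modulation and overlap categories, spatial
#' coding metrics per unit, and the pHFO spatial-impact analyses (shuffle
#' null and targeted down-sampling). When `session` is `NULL` a synthetic
#' session is simulated from `spec`. The control reference defaults to
#' the features of a simulated control session (same spec with the pHFO
#' rate set to zero).
#'
#' All resampling seeds are derived from `seed` and recorded in the
#' report, so every number is reproducible.
#'
#' @param session An `hfo_session` (or a list with the same components,
#'   e.g. from [read_session()]), or `NULL` to simulate.
#' @param spec A [session_spec()] used when `session` is `NULL`.
#' @param control_features Control-ripple feature data frame
#'   (`envelope_uV`, `peak_freq_hz`), or `NULL` to synthesise one.
#' @param seed Integer master seed.
#' @param out_dir Optional directory; stage outputs are written as CSV.
#' @return List of class `session_report`; see Details.
#' @details The report contains: `events` (labelled event table),
#'   `event_summary` (per-class counts and feature medians/IQRs, amplitude
#'   CV), `theta` (per-event peri-pHFO table), `modulation` (per
#'   unit/class), `categories` (overlap), `spatial` (per unit/epoch
#'   metrics), `impact` (shuffle verdicts and down-sampling results per
#'   eligible unit), and `seeds`.
#' @export
run_session <- function(session = NULL, spec = session_spec(),
                        control_features = NULL, seed = 1L,
                        out_dir = NULL) {
  seed <- as.integer(seed)
  seeds <- list(session = seed, control = seed + 500000L,
                shuffle = seed + 600000L, downsample = seed + 700000L)
  if (is.null(session)) session <- simulate_session(spec, seeds$session)
  log_msg <- function(...) message(sprintf(...))

  events <- detect_hfo(session$lfp_pyr, session$epochs)
  log_msg("detection: %d events", nrow(events))

  if (is.null(control_features)) {
    cspec <- session$spec
    cspec$phfo_rate_hz <- 0
    ctl <- simulate_session(cspec, seeds$control)
    cev <- detect_hfo(ctl$lfp_pyr, ctl$epochs)
    control_features <- extract_features(ctl$lfp_pyr, cev)
    log_msg("control reference: %d events", nrow(control_features))
  }
  labelled <- classify_events(session$lfp_pyr, events, control_features)
  n_phfo <- sum(labelled$label == "pHFO")
  log_msg("classification: %d ripple-like, %d pHFO",
          sum(labelled$label == "ripple-like"), n_phfo)

  qs <- function(x) stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  event_summary <- do.call(rbind, lapply(split(labelled, labelled$label),
    function(d) {
      f <- qs(d$peak_freq_hz); e <- qs(d$envelope_uV)
      data.frame(label = d$label[1], n = nrow(d), freq_median_hz = f[2],
                 freq_iqr_lo = f[1], freq_iqr_hi = f[3],
                 env_median_uV = e[2], env_iqr_lo = e[1], env_iqr_hi = e[3])
    }))
  cv <- if (nrow(labelled) >= 20) amplitude_cv(labelled) else NA_real_

  theta <- theta_around_events(session$lfp_rad, labelled, session$track)
  log_msg("theta: %d pHFO events analysed, %d with onset phase",
          nrow(theta), sum(theta$included))

  mod <- unit_modulation(session$spikes, labelled)
  categories <- modulation_categories(mod)

  ep <- session$epochs
  spatial <- list(); impact <- list()
  for (i in which(ep$label == "forage")) {
    tr <- session$track[session$track$time_s >= ep$start_s[i] &
                        session$track$time_s < ep$end_s[i], , drop = FALSE]
    ctx <- map_context(tr)
    ph <- labelled$peak_time_s[labelled$label == "pHFO" &
                               labelled$peak_time_s >= ep$start_s[i] &
                               labelled$peak_time_s < ep$end_s[i]]
    for (u in sort(unique(session$spikes$unit_id))) {
      st <- session$spikes$time_s[session$spikes$unit_id == u]
      st <- st[st >= ep$start_s[i] & st < ep$end_s[i]]
      map <- build_rate_map(st, ctx)
      active <- !is.na(map$peak_hz) && map$peak_hz > 2
      spatial[[length(spatial) + 1L]] <- data.frame(
        unit_id = u, epoch = i, n_spikes = length(st),
        peak_hz = map$peak_hz,
        info_bits = if (active) spatial_information(map) else NA_real_,
        splithalf_r = if (active) suppressWarnings(
          split_half_correlation(st, tr)) else NA_real_,
        sparsity = if (active) spatial_sparsity(map) else NA_real_,
        active = active)
      if (length(ph) > 15 && length(st) > 0 &&
          sum(in_event_core(st, ph)) / length(st) >= 0.01) {
        ds <- targeted_downsample(st, ph, ctx, seed = seeds$downsample + u)
        impact[[length(impact) + 1L]] <- data.frame(
          unit_id = u, epoch = i, percent_in_phfo = ds$percent_in_phfo,
          info_original = ds$info_original,
          info_targeted = ds$info_targeted,
          improvement = ds$improvement, significant = ds$significant)
      }
    }
    if (length(ph) > 15) {
      sh <- shuffle_event_info(ph, ctx, seed = seeds$shuffle + i)
      impact[[length(impact) + 1L]] <- data.frame(
        unit_id = NA_integer_, epoch = i, percent_in_phfo = NA_real_,
        info_original = sh$information, info_targeted = NA_real_,
        improvement = NA_real_,
        significant = sh$verdict != "inside")
      log_msg("epoch %d: pHFO map info %.3f bits (%s the shuffle band)",
              i, sh$information, sh$verdict)
    } else {
      log_msg("epoch %d: no pHFO spatial impact (%d pHFOs <= 15)",
              i, length(ph))
    }
  }
  spatial <- do.call(rbind, spatial)
  impact <- if (length(impact)) do.call(rbind, impact) else NULL

  report <- structure(list(
    events = labelled, event_summary = event_summary, amplitude_cv = cv,
    theta = theta, modulation = mod, categories = categories,
    spatial = spatial, impact = impact, seeds = seeds),
    class = "session_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_table(labelled, file.path(out_dir, "events.csv"))
    write_table(theta, file.path(out_dir, "theta.csv"))
    write_table(mod, file.path(out_dir, "modulation.csv"))
    write_table(categories, file.path(out_dir, "categories.csv"))
    write_table(spatial, file.path(out_dir, "spatial.csv"))
    if (!is.null(impact)) write_table(impact, file.path(out_dir, "impact.csv"))
    jsonlite::write_json(report_summary(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

report_summary <- function(report) {
  cat_tab <- table(report$categories$category)
  list(
    n_events = nrow(report$events),
    events = report$event_summary,
    amplitude_cv = report$amplitude_cv,
    theta_n = nrow(report$theta),
    prop_modulated = vapply(split(report$modulation,
                                  report$modulation$event_class),
                            function(d) mean(d$modulated), numeric(1)),
    categories = as.list(cat_tab),
    prop_active = if (nrow(report$spatial))
      active_proportion(split(report$spatial$peak_hz,
                              report$spatial$unit_id)) else NA,
    seeds = report$seeds)
}

#' @export
print.session_report <- function(x, ...) {
  cat("session_report\n")
  print(x$event_summary, row.names = FALSE)
  cat(sprintf("amplitude CV: %.3f\n", x$amplitude_cv))
  if (nrow(x$modulation)) {
    pm <- vapply(split(x$modulation, x$modulation$event_class),
                 function(d) mean(d$modulated), numeric(1))
    cat("proportion modulated:",
        paste(sprintf("%s %.2f", names(pm), pm), collapse = ", "), "\n")
  }
  if (!is.null(x$spatial) && nrow(x$spatial))
    cat(sprintf("active units: %.2f; median info (active): %.2f bits\n",
                active_proportion(split(x$spatial$peak_hz, x$spatial$unit_id)),
                stats::median(x$spatial$info_bits, na.rm = TRUE)))
  invisible(x)
}
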