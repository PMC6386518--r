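#' Spatial map of pHFO event positions
#'
#' Treats pHFO events as a point process over the animal's position and
#' builds an event-rate map (events per second of occupancy) with exactly
#' the binning, smoothing and visited rules of the spike rate maps, then
#' scores its spatial information. Requires more than `min_events`
#' events.
#'
#' @param event_times Numeric pHFO times (s) within the tracked epoch.
#' @param track Position track of the epoch, or a [map_context()].
#' @param min_events Minimum event count (exclusive).
#' @return List: `map` (a `rate_map`), `information` (bits),
#'   `n_events`.
#' @export
event_rate_map <- function(event_times, track, min_events = 15L) {
  if (length(event_times) <= min_events)
    stop("event map requires more than ", min_events, " events (got ",
         length(event_times), ")")
  ctx <- if (inherits(track, "map_context")) track else map_context(track)
  map <- build_rate_map(event_times, ctx)
  list(map = map, information = spatial_information(map),
       n_events = length(event_times))
}

# information directly from per-bin counts under a fixed context
info_from_counts <- function(ctx, counts) {
  vb <- which(ctx$visited)
  raw <- counts[vb] / ctx$occupancy_s[vb]
  sm <- as.numeric(ctx$smooth %*% raw)
  P <- ctx$occupancy_s[vb] / sum(ctx$occupancy_s[vb])
  Rbar <- sum(P * sm)
  if (Rbar <= 0) return(NA_real_)
  ratio <- sm / Rbar
  sum(ifelse(sm > 0, P * ratio * log2(ratio), 0))
}

#' Shuffle null for pHFO spatial information
#'
#' Redraws the event times uniformly from the tracked samples of the
#' epoch (occupancy-weighted) `n_shuffles` times, recomputes the spatial
#' information of the event map for each draw with identical map
#' parameters, and compares the actual information with the 5th-95th
#' percentile band of the null distribution.
#'
#' @param event_times Numeric pHFO times (s).
#' @param track Position track of the epoch.
#' @param n_shuffles Number of shuffles (default 1000).
#' @param seed Integer seed.
#' @param min_events Minimum event count (exclusive).
#' @return Object of class `shuffle_result`: `information`, `null`
#'   (numeric vector), `band` (5th/95th percentiles), `verdict`
#'   (`"inside"`, `"above"`, `"below"`), `n_events`, `seed`.
#' @export
shuffle_event_info <- function(event_times, track, n_shuffles = 1000L,
                               seed = 1L, min_events = 15L) {
  if (n_shuffles < 1L) stop("n_shuffles must be positive")
  ctx <- if (inherits(track, "map_context")) track else map_context(track)
  erm <- event_rate_map(event_times, ctx, min_events)
  nev <- length(event_times)
  nb <- ctx$nx * ctx$ny
  null <- with_seed(seed, {
    vapply(seq_len(n_shuffles), function(i) {
      s <- sample(ctx$sample_bin, nev, replace = TRUE)
      info_from_counts(ctx, tabulate(s, nbins = nb))
    }, numeric(1))
  })
  band <- stats::quantile(null, c(0.05, 0.95), names = FALSE, na.rm = TRUE)
  verdict <- if (erm$information > band[2]) "above"
  else if (erm$information < band[1]) "below" else "inside"
  structure(list(information = erm$information, null = null, band = band,
                 verdict = verdict, n_events = nev, seed = seed),
            class = "shuffle_result")
}

#' @export
print.shuffle_result <- function(x, ...) {
  cat(sprintf(
    "shuffle_result: info %.3f bits vs null band [%.3f, %.3f] -> %s (n = %d events, %d shuffles)\n",
    x$information, x$band[1], x$band[2], x$verdict, x$n_events,
    length(x$null)))
  invisible(x)
}

#' Targeted versus random spike down-sampling
#'
#' Removes the spikes emitted during pHFOs (the 100 ms core around each
#' event) from a unit's map and measures the change in spatial
#' information; compares that improvement with the distribution obtained
#' by removing an equal number of randomly chosen spikes (`n_random`
#' draws), all maps built with identical parameters. The improvement is
#' significant when it exceeds the 95th percentile of the random-removal
#' distribution. Requires that at least `min_fraction` of the unit's
#' spikes occur during pHFOs.
#'
#' @param spike_times Spike times (s) of one unit within the epoch.
#' @param event_times pHFO times (s).
#' @param track Position track of the epoch, or a [map_context()].
#' @param n_random Number of random down-samples.
#' @param seed Integer seed.
#' @param min_fraction Minimum fraction of spikes during pHFOs.
#' @return Object of class `downsample_result`: `n_spikes`,
#'   `n_spikes_in_phfo`, `percent_in_phfo`, `info_original`,
#'   `info_targeted`, `improvement`, `null_improvement` (vector),
#'   `threshold` (95th percentile), `significant`, `seed`.
#' @export
targeted_downsample <- function(spike_times, event_times, track,
                                n_random = 1000L, seed = 1L,
                                min_fraction = 0.01) {
  ctx <- if (inherits(track, "map_context")) track else map_context(track)
  nb <- ctx$nx * ctx$ny
  inphfo <- in_event_core(spike_times, event_times)
  n_in <- sum(inphfo)
  n_tot <- length(spike_times)
  if (n_in == 0) stop("no spikes occur during pHFOs")
  if (n_in / n_tot < min_fraction)
    stop(sprintf("only %.2f%% of spikes occur during pHFOs (minimum %g%%)",
                 100 * n_in / n_tot, 100 * min_fraction))
  sbin <- ctx$sample_bin[nearest_index(ctx$time_s, spike_times)]
  counts_all <- tabulate(sbin, nbins = nb)
  info_orig <- info_from_counts(ctx, counts_all)
  counts_targ <- counts_all - tabulate(sbin[inphfo], nbins = nb)
  info_targ <- info_from_counts(ctx, counts_targ)
  null <- with_seed(seed, {
    vapply(seq_len(n_random), function(i) {
      drop <- sample.int(n_tot, n_in)
      info_from_counts(ctx, counts_all - tabulate(sbin[drop], nbins = nb)) -
        info_orig
    }, numeric(1))
  })
  thr <- stats::quantile(null, 0.95, names = FALSE, na.rm = TRUE)
  imp <- info_targ - info_orig
  structure(list(n_spikes = n_tot, n_spikes_in_phfo = n_in,
                 percent_in_phfo = 100 * n_in / n_tot,
                 info_original = info_orig, info_targeted = info_targ,
                 improvement = imp, null_improvement = null,
                 threshold = thr, significant = imp > thr, seed = seed),
            class = "downsample_result")
}

#' @export
print.downsample_result <- function(x, ...) {
  cat(sprintf(
    "downsample_result: %d/%d spikes in pHFOs (%.1f%%); info %.3f -> %.3f (improvement %.3f, null 95th %.3f)%s\n",
    x$n_spikes_in_phfo, x$n_spikes, x$percent_in_phfo, x$info_original,
    x$info_targeted, x$improvement, x$threshold,
    if (x$significant) " *" else ""))
  invisible(x)
}

#' Improvement as a function of the pHFO spike fraction
#'
#' Ordinary least-squares fit of the spatial-information improvement
#' against the percentage of spikes removed, restricted to units whose
#' targeted down-sampling was significant.
#'
#' @param results List of `downsample_result` objects, or a data frame
#'   with columns `percent_in_phfo`, `improvement`, `significant`.
#' @return List: `slope`, `intercept`, `r_squared`, `n`.
#' @export
improvement_vs_fraction <- function(results) {
  df <- if (is.data.frame(results)) results else
    do.call(rbind, lapply(results, function(r)
      data.frame(percent_in_phfo = r$percent_in_phfo,
                 improvement = r$improvement, significant = r$significant)))
  df <- df[df$significant, , drop = FALSE]
  if (nrow(df) < 3L)
    stop("fit requires at least 3 significant units (got ", nrow(df), ")")
  fit <- stats::lm(improvement ~ percent_in_phfo, data = df)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = summary(fit)$r.squared, n = nrow(df))
}
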