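#' Peri-event firing-rate matrix
#'
#' Spikes within 500 ms of each event are binned into 20 ms bins and
#' converted to rates; each event contributes one row, treated downstream
#' as an independent observation (events closer than 1 s still get their
#' own rows). The per-event spike-time offsets are retained so window
#' means can be computed on exact window edges rather than bin edges.
#'
#' @param spike_times Numeric spike times (s) of one unit.
#' @param event_times Numeric event times (s).
#' @param half_window_s Half-width of the peri-event window.
#' @param bin_s Bin width.
#' @return Object of class `peri_event_rates`: `rates` (events x bins
#'   matrix, Hz), `offsets` (list of per-event spike offsets), `bin_s`,
#'   `half_window_s`, `bin_centers_s`.
#' @export
peri_event_rates <- function(spike_times, event_times, half_window_s = 0.5,
                             bin_s = 0.02) {
  if (!length(event_times)) stop("at least one event is required")
  spike_times <- sort(spike_times)
  nb <- round(2 * half_window_s / bin_s)
  edges <- seq(-half_window_s, half_window_s, length.out = nb + 1L)
  rates <- matrix(0, length(event_times), nb)
  offsets <- vector("list", length(event_times))
  for (i in seq_along(event_times)) {
    lo <- findInterval(event_times[i] - half_window_s, spike_times) + 1L
    hi <- findInterval(event_times[i] + half_window_s, spike_times)
    off <- if (hi >= lo) spike_times[lo:hi] - event_times[i] else numeric(0)
    offsets[[i]] <- off
    if (length(off)) {
      b <- pmin(pmax(findInterval(off, edges, rightmost.closed = TRUE), 1L), nb)
      rates[i, ] <- tabulate(b, nbins = nb) / bin_s
    }
  }
  structure(list(rates = rates, offsets = offsets, bin_s = bin_s,
                 half_window_s = half_window_s,
                 bin_centers_s = (edges[-1] + edges[-length(edges)]) / 2),
            class = "peri_event_rates")
}

#' Signed-rank test for event modulation of a unit
#'
#' Pairs, per event, the baseline rate (mean over 500 to 400 ms before
#' the event) with the during-event rate (mean over the 100 ms centred on
#' the event) and applies a two-sided Wilcoxon signed-rank test. A unit
#' is modulated when p < 0.05. Requires at least `min_events` events.
#' When every pair is tied the statistic is undefined and the unit is
#' reported unmodulated with p = 1.
#'
#' @param per A [peri_event_rates()] object.
#' @param min_events Minimum number of events.
#' @param alpha Significance level for the modulated flag.
#' @return List of class `modulation_result`: `n_events`, `rate_bl_hz`,
#'   `rate_event_hz`, `p_value`, `modulated`, `direction`.
#' @export
modulation_test <- function(per, min_events = 10L, alpha = 0.05) {
  stopifnot(inherits(per, "peri_event_rates"))
  n <- length(per$offsets)
  if (n < min_events)
    stop("modulation test requires at least ", min_events, " events (got ",
         n, ")")
  bl <- vapply(per$offsets, function(o)
    sum(o >= -0.5 & o < -0.4) / 0.1, numeric(1))
  dur <- vapply(per$offsets, function(o)
    sum(o >= -0.05 & o < 0.05) / 0.1, numeric(1))
  d <- dur - bl
  if (all(d == 0)) {
    p <- 1
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(dur, bl, paired = TRUE, exact = FALSE)$p.value)
    if (!is.finite(p)) p <- 1
  }
  structure(list(n_events = n, rate_bl_hz = mean(bl),
                 rate_event_hz = mean(dur), p_value = p,
                 modulated = p < alpha,
                 direction = sign(stats::median(d[d != 0]))),
            class = "modulation_result")
}

#' Modulation of every unit by every event class
#'
#' Runs [peri_event_rates()] and [modulation_test()] for each unit and
#' each event class; units observed with fewer than `min_events` events
#' of a class get no row for that class.
#'
#' @param spikes Data frame `unit_id`, `time_s`.
#' @param events Labelled events data frame (`peak_time_s`, `label`).
#' @param min_events Minimum events per class.
#' @return Data frame: `unit_id`, `event_class`, `n_events`,
#'   `rate_bl_hz`, `rate_event_hz`, `p_value`, `modulated`.
#' @export
unit_modulation <- function(spikes, events, min_events = 10L) {
  classes <- unique(events$label)
  units <- sort(unique(spikes$unit_id))
  rows <- list()
  for (u in units) {
    st <- spikes$time_s[spikes$unit_id == u]
    for (cl in classes) {
      et <- events$peak_time_s[events$label == cl]
      if (length(et) < min_events) next
      res <- modulation_test(peri_event_rates(st, et), min_events)
      rows[[length(rows) + 1L]] <- data.frame(
        unit_id = u, event_class = cl, n_events = res$n_events,
        rate_bl_hz = res$rate_bl_hz, rate_event_hz = res$rate_event_hz,
        p_value = res$p_value, modulated = res$modulated)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(unit_id = integer(0), event_class = character(0),
                      n_events = integer(0), rate_bl_hz = numeric(0),
                      rate_event_hz = numeric(0), p_value = numeric(0),
                      modulated = logical(0))
  out
}

#' Which event types modulate a unit
#'
#' Deterministic category from the two modulation flags: `ripple-like
#' only`, `pHFO only`, `both`, or `neither`. Returns `NA` when either
#' class result is missing (fewer than the minimum events).
#'
#' @param ripple_mod,phfo_mod Logical flags (may be `NA`).
#' @return Character category or `NA`.
#' @export
modulation_overlap <- function(ripple_mod, phfo_mod) {
  mapply(function(r, p) {
    if (is.na(r) || is.na(p)) return(NA_character_)
    if (r && p) "both"
    else if (r) "ripple-like only"
    else if (p) "pHFO only"
    else "neither"
  }, ripple_mod, phfo_mod, USE.NAMES = FALSE)
}

#' Modulation-overlap table across units
#'
#' @param mod Data frame from [unit_modulation()].
#' @return Data frame `unit_id`, `category` for units with results for
#'   both a ripple-like and a pHFO class.
#' @export
modulation_categories <- function(mod) {
  units <- sort(unique(mod$unit_id))
  get <- function(u, cl) {
    i <- which(mod$unit_id == u & mod$event_class == cl)
    if (length(i)) mod$modulated[i[1]] else NA
  }
  data.frame(unit_id = units,
             category = modulation_overlap(
               vapply(units, get, logical(1), cl = "ripple-like"),
               vapply(units, get, logical(1), cl = "pHFO")))
}
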