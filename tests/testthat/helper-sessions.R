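# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

# default synthetic epileptic session + detection + classification,
# reused by the detection, classification and acceptance tests
default_session <- function() {
  if (is.null(.fixtures$ses)) .fixtures$ses <- simulate_session(session_spec(), seed = 1L)
  .fixtures$ses
}

default_events <- function() {
  if (is.null(.fixtures$ev)) {
    ses <- default_session()
    .fixtures$ev <- detect_hfo(ses$lfp_pyr, ses$epochs)
  }
  .fixtures$ev
}

control_reference <- function() {
  if (is.null(.fixtures$ctl)) {
    spec <- session_spec(phfo_rate_hz = 0)
    ctl <- simulate_session(spec, seed = 101L)
    cev <- detect_hfo(ctl$lfp_pyr, ctl$epochs)
    .fixtures$ctl <- extract_features(ctl$lfp_pyr, cev)
  }
  .fixtures$ctl
}

labelled_events <- function() {
  if (is.null(.fixtures$lab)) {
    ses <- default_session()
    .fixtures$lab <- classify_events(ses$lfp_pyr, default_events(),
                                     control = control_reference())
  }
  .fixtures$lab
}

# index of the matching scheduled event (within tol seconds), or NA
match_truth <- function(times, truth, tol = 0.05) {
  vapply(times, function(t) {
    i <- which.min(abs(truth$time_s - t))
    if (abs(truth$time_s[i] - t) < tol) i else NA_integer_
  }, integer(1))
}

# single foraging epoch spec used by spatial / impact tests
forage_spec <- function(duration_s = 600) {
  session_spec(epochs = data.frame(label = "forage",
                                   duration_s = duration_s))
}

forage_track <- function() {
  if (is.null(.fixtures$ftrack))
    .fixtures$ftrack <- generate_trajectory(forage_spec(), seed = 3L)
  .fixtures$ftrack
}

forage_context <- function() {
  if (is.null(.fixtures$fctx))
    .fixtures$fctx <- map_context(forage_track())
  .fixtures$fctx
}

# empty ground-truth table (for LFP/spike synthesis without events)
no_events <- function() {
  data.frame(time_s = numeric(0), class = character(0),
             freq_hz = numeric(0), amp_uV = numeric(0),
             env_uV = numeric(0), speed_cm_s = numeric(0))
}

# circular absolute difference of two angles
circ_diff <- function(a, b) {
  abs(((a - b + pi) %% (2 * pi)) - pi)
}
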