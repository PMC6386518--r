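#' Write / read an LFP trace as flat binary with a JSON sidecar
#'
#' Samples are stored little-endian float32 in `<path>`; the sidecar
#' `<path>.json` records the sampling rate, units (microvolts) and
#' anatomical layer.
#'
#' @param lfp An [lfp_signal()].
#' @param path Output file path.
#' @return `path`, invisibly (`write_lfp`); an `lfp_signal` (`read_lfp`).
#' @export
write_lfp <- function(lfp, path) {
  stopifnot(inherits(lfp, "lfp_signal"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(lfp$samples), con, size = 4L, endian = "little")
  jsonlite::write_json(
    list(rate_hz = lfp$rate_hz, units = "uV", layer = lfp$layer,
         n_samples = length(lfp$samples)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_lfp
#' @export
read_lfp <- function(path) {
  meta_path <- paste0(path, ".json")
  if (!file.exists(meta_path))
    stop("missing LFP sidecar: ", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  con <- file(path, "rb")
  on.exit(close(con))
  x <- readBin(con, numeric(), n = meta$n_samples, size = 4L,
               endian = "little")
  lfp_signal(x, meta$rate_hz, meta$layer)
}

# CSV helpers: all tables carry headers; times s, voltages uV, positions cm
write_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

read_table <- function(path, required = NULL) {
  if (!file.exists(path)) stop("missing file: ", path)
  df <- utils::read.csv(path)
  if (!is.null(required) && !all(required %in% names(df)))
    stop("file ", path, " lacks required columns: ",
         paste(setdiff(required, names(df)), collapse = ", "))
  df
}

#' Write or read a complete session directory
#'
#' Serialises a simulated (or assembled) session to plain formats: LFP as
#' float32 binary plus JSON sidecars, spikes as `unit_id,time_s` CSV,
#' tracking as `time_s,x_cm,y_cm` CSV, epochs as `label,start_s,end_s`
#' CSV, and ground truth (when present) as CSV.
#'
#' @param session An `hfo_session` from [simulate_session()].
#' @param dir Output directory (created if needed).
#' @return `dir` invisibly (`write_session`); a list with the session
#'   components (`read_session`).
#' @export
write_session <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_lfp(session$lfp_pyr, file.path(dir, "lfp_pyramidale.f32"))
  write_lfp(session$lfp_rad, file.path(dir, "lfp_radiatum.f32"))
  write_table(session$spikes, file.path(dir, "spikes.csv"))
  write_table(session$track[, c("time_s", "x_cm", "y_cm", "epoch")],
              file.path(dir, "tracking.csv"))
  write_table(session$epochs, file.path(dir, "epochs.csv"))
  if (!is.null(session$truth))
    write_table(session$truth, file.path(dir, "ground_truth.csv"))
  if (!is.null(session$units))
    write_table(session$units, file.path(dir, "units.csv"))
  invisible(dir)
}

#' @rdname write_session
#' @export
read_session <- function(dir) {
  track <- read_table(file.path(dir, "tracking.csv"),
                      c("time_s", "x_cm", "y_cm"))
  track$speed_cm_s <- compute_speed(track)
  class(track) <- c("position_track", "data.frame")
  truth_path <- file.path(dir, "ground_truth.csv")
  units_path <- file.path(dir, "units.csv")
  list(lfp_pyr = read_lfp(file.path(dir, "lfp_pyramidale.f32")),
       lfp_rad = read_lfp(file.path(dir, "lfp_radiatum.f32")),
       spikes = read_table(file.path(dir, "spikes.csv"),
                           c("unit_id", "time_s")),
       track = track,
       epochs = read_table(file.path(dir, "epochs.csv"),
                           c("label", "start_s", "end_s")),
       truth = if (file.exists(truth_path)) read_table(truth_path) else NULL,
       units = if (file.exists(units_path)) read_table(units_path) else NULL)
}
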