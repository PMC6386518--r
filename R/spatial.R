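#' Smoothing kernel for firing-rate maps
#'
#' The 5 x 5 bin Gaussian kernel (standard deviation of approximately one
#' bin) applied to all spatial rate maps. The kernel sums to exactly 1, so
#' smoothing conserves the mean rate over interior regions.
#'
#' @return A 5 x 5 numeric matrix summing to 1.
#' @export
rate_map_kernel <- function() {
  k <- c(0.0025, 0.0125, 0.0200, 0.0125, 0.0025,
         0.0125, 0.0625, 0.1000, 0.0625, 0.0125,
         0.0200, 0.1000, 0.1600, 0.1000, 0.0200,
         0.0125, 0.0625, 0.1000, 0.0625, 0.0125,
         0.0025, 0.0125, 0.0200, 0.0125, 0.0025)
  matrix(k, nrow = 5, byrow = TRUE)
}

#' Running speed from a position track
#'
#' Positions are smoothed with a centred moving average (default 250 ms)
#' before central-difference differentiation, which suppresses tracking
#' jitter that would otherwise inflate speed.
#'
#' @param track Data frame with columns `time_s`, `x_cm`, `y_cm`.
#' @param smooth_s Width of the position-smoothing window in seconds.
#' @return Numeric vector of speeds (cm/s), one per track sample.
#' @export
compute_speed <- function(track, smooth_s = 0.25) {
  stopifnot(is.data.frame(track), nrow(track) >= 2)
  t <- track$time_s
  dt <- stats::median(diff(t))
  k <- max(1L, round(smooth_s / dt))
  xs <- running_mean(track$x_cm, k)
  ys <- running_mean(track$y_cm, k)
  n <- length(t)
  # central difference; one-sided at the ends
  i0 <- c(1L, seq_len(n - 2L), n - 1L)
  i1 <- c(2L, seq_len(n - 2L) + 2L, n)
  sp <- sqrt((xs[i1] - xs[i0])^2 + (ys[i1] - ys[i0])^2) / (t[i1] - t[i0])
  pmax(sp, 0)
}

# centred moving average with edge-shrunk windows
running_mean <- function(x, k) {
  if (k <= 1L) return(x)
  n <- length(x)
  cs <- cumsum(c(0, x))
  half <- k %/% 2
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Spatial binning context for a tracked epoch
#'
#' Precomputes everything the rate-map machinery needs for one epoch of
#' tracking: the 5 cm bin grid anchored at the bounding-box corner of the
#' path, per-bin occupancy, the visited mask (bins within 2.5 cm of the
#' path and occupied for at least 150 ms), the bin index of every track
#' sample, and a linear smoothing operator implementing the 5 x 5 Gaussian
#' kernel renormalised over the visited support. Resampling procedures
#' (shuffles, down-sampling) reuse one context so that map parameters are
#' identical across all maps they compare.
#'
#' @param track Data frame with `time_s`, `x_cm`, `y_cm`.
#' @param bin_cm Bin side length (cm).
#' @param min_occupancy_s Minimum occupancy for a bin to count as visited.
#' @param path_distance_cm Maximum distance from bin centre to the path.
#' @param bounds Optional named list `x0`, `y0`, `nx`, `ny` fixing the
#'   grid; used to put several maps (e.g. session halves) on one grid.
#' @return An object of class `map_context`.
#' @export
map_context <- function(track, bin_cm = 5, min_occupancy_s = 0.15,
                        path_distance_cm = 2.5, bounds = NULL) {
  stopifnot(nrow(track) >= 2)
  x <- track$x_cm; y <- track$y_cm; t <- track$time_s
  dt <- stats::median(diff(t))
  if (is.null(bounds)) {
    x0 <- min(x); y0 <- min(y)
    nx <- max(1L, ceiling((max(x) - x0) / bin_cm + 1e-9))
    ny <- max(1L, ceiling((max(y) - y0) / bin_cm + 1e-9))
  } else {
    x0 <- bounds$x0; y0 <- bounds$y0; nx <- bounds$nx; ny <- bounds$ny
  }
  ix <- pmin(pmax(floor((x - x0) / bin_cm), 0L), nx - 1L)
  iy <- pmin(pmax(floor((y - y0) / bin_cm), 0L), ny - 1L)
  bin <- as.integer(ix + nx * iy + 1L)            # column-major over (x fast)
  nb <- as.integer(nx * ny)
  occ <- numeric(nb)
  tb <- tabulate(bin, nbins = nb)
  occ <- tb * dt
  # visited: occupancy rule + distance from bin centre to nearest path sample
  cx <- x0 + (rep(seq_len(nx), ny) - 0.5) * bin_cm
  cy <- y0 + (rep(seq_len(ny), each = nx) - 0.5) * bin_cm
  near <- rep(FALSE, nb)
  cand <- which(occ > 0)
  # only candidate bins and their neighbours can be near the path
  for (b in cand) near[b] <- TRUE
  chk <- which(!near)
  if (length(chk)) {
    # a bin with zero occupancy can still be within 2.5 cm of the path
    # (path clipping a corner); check those adjacent to occupied bins
    adj <- unique(unlist(lapply(cand, function(b) {
      bx <- (b - 1L) %% nx; by <- (b - 1L) %/% nx
      nbr <- expand.grid(dx = -1:1, dy = -1:1)
      ok <- bx + nbr$dx >= 0 & bx + nbr$dx < nx & by + nbr$dy >= 0 & by + nbr$dy < ny
      (bx + nbr$dx[ok]) + nx * (by + nbr$dy[ok]) + 1L
    })))
    adj <- setdiff(adj, cand)
    for (b in adj) {
      d2 <- (x - cx[b])^2 + (y - cy[b])^2
      if (min(d2) < path_distance_cm^2) near[b] <- TRUE
    }
  }
  visited <- near & occ >= min_occupancy_s
  S <- smoothing_operator(nx, ny, visited)
  structure(list(nx = nx, ny = ny, bin_cm = bin_cm, origin = c(x0, y0),
                 occupancy_s = occ, visited = visited, sample_bin = bin,
                 dt = dt, smooth = S, time_s = t),
            class = "map_context")
}

# dense linear operator: smoothed[v] = S %*% raw[v] over visited bins,
# kernel renormalised over visited support
smoothing_operator <- function(nx, ny, visited) {
  k <- rate_map_kernel()
  vb <- which(visited)
  nv <- length(vb)
  S <- matrix(0, nv, nv)
  pos <- match(seq_len(nx * ny), vb)    # bin -> visited index
  bx <- (vb - 1L) %% nx; by <- (vb - 1L) %/% nx
  for (i in seq_len(nv)) {
    wsum <- 0; row <- numeric(nv)
    for (dy in -2:2) for (dx in -2:2) {
      jx <- bx[i] + dx; jy <- by[i] + dy
      if (jx < 0 || jx >= nx || jy < 0 || jy >= ny) next
      j <- jx + nx * jy + 1L
      if (!visited[j]) next
      w <- k[dy + 3L, dx + 3L]
      row[pos[j]] <- row[pos[j]] + w
      wsum <- wsum + w
    }
    S[i, ] <- row / wsum
  }
  S
}

#' Firing-rate map of a unit over an epoch
#'
#' Raw rate per 5 x 5 cm bin is total spikes divided by total occupancy
#' time; the raw map is then smoothed with the 5 x 5 Gaussian kernel
#' (renormalised over visited bins). Bins never within 2.5 cm of the
#' tracked path or occupied for less than 150 ms are unvisited and carry
#' `NA` in both maps. Spikes are assigned the position of the nearest
#' tracking sample in time.
#'
#' @param spike_times Numeric vector of spike times (s).
#' @param track Position track data frame, or a precomputed [map_context()].
#' @param bin_cm Bin side length (cm).
#' @return An object of class `rate_map` with elements `rate` (smoothed,
#'   Hz), `raw`, `counts`, `occupancy_s`, `visited`, `peak_hz` (peak of the
#'   smoothed map), `bin_cm`, `origin`.
#' @export
build_rate_map <- function(spike_times, track, bin_cm = 5) {
  ctx <- if (inherits(track, "map_context")) track else map_context(track, bin_cm)
  counts <- counts_from_times(ctx, spike_times)
  map_from_counts(ctx, counts)
}

counts_from_times <- function(ctx, times) {
  if (!length(times)) return(integer(ctx$nx * ctx$ny))
  idx <- nearest_index(ctx$time_s, times)
  tabulate(ctx$sample_bin[idx], nbins = ctx$nx * ctx$ny)
}

map_from_counts <- function(ctx, counts) {
  nb <- ctx$nx * ctx$ny
  raw <- rep(NA_real_, nb)
  vb <- which(ctx$visited)
  raw[vb] <- counts[vb] / ctx$occupancy_s[vb]
  sm <- rep(NA_real_, nb)
  sm[vb] <- as.numeric(ctx$smooth %*% raw[vb])
  dimr <- c(ctx$nx, ctx$ny)
  structure(list(rate = array(sm, dimr), raw = array(raw, dimr),
                 counts = array(counts, dimr),
                 occupancy_s = array(ctx$occupancy_s, dimr),
                 visited = array(ctx$visited, dimr),
                 peak_hz = if (length(vb)) max(sm[vb]) else NA_real_,
                 bin_cm = ctx$bin_cm, origin = ctx$origin),
            class = "rate_map")
}

#' Construct a rate map directly from matrices
#'
#' Low-level constructor used for analytic maps in tests and examples;
#' the supplied rate matrix is taken as already smoothed.
#'
#' @param rate Matrix of firing rates (Hz); `NA` marks unvisited bins.
#' @param occupancy_s Matrix of occupancy times (s), same shape.
#' @return A `rate_map` object.
#' @export
rate_map <- function(rate, occupancy_s) {
  rate <- as.matrix(rate); occupancy_s <- as.matrix(occupancy_s)
  stopifnot(all(dim(rate) == dim(occupancy_s)))
  visited <- !is.na(rate) & occupancy_s > 0
  structure(list(rate = rate, raw = rate, counts = NULL,
                 occupancy_s = occupancy_s, visited = visited,
                 peak_hz = suppressWarnings(max(rate[visited])),
                 bin_cm = NA_real_, origin = c(NA_real_, NA_real_)),
            class = "rate_map")
}

#' @export
print.rate_map <- function(x, ...) {
  cat(sprintf("rate_map: %d x %d bins, %d visited, peak %.2f Hz\n",
              nrow(x$rate), ncol(x$rate), sum(x$visited), x$peak_hz))
  invisible(x)
}

#' Spatial information score (bits per spike)
#'
#' Skaggs information `I = sum_i P_i (R_i/R) log2(R_i/R)` where `P_i` is
#' the occupancy probability of bin `i`, `R_i` its firing rate and `R` the
#' occupancy-weighted mean rate. Zero-rate bins contribute zero.
#'
#' @param map A `rate_map`.
#' @return Information in bits per spike.
#' @export
spatial_information <- function(map) {
  v <- map$visited
  P <- map$occupancy_s[v] / sum(map$occupancy_s[v])
  R <- map$rate[v]
  Rbar <- sum(P * R)
  if (!is.finite(Rbar) || Rbar <= 0)
    stop("spatial information undefined: mean rate is zero")
  ratio <- R / Rbar
  terms <- ifelse(R > 0, P * ratio * log2(ratio), 0)
  sum(terms)
}

#' Spatial sparsity
#'
#' `(sum_i P_i R_i)^2 / sum_i P_i R_i^2`; equals 1 for a spatially uniform
#' map and approaches the occupancy fraction of the active region for a
#' concentrated field.
#'
#' @param map A `rate_map`.
#' @return Sparsity in (0, 1].
#' @export
spatial_sparsity <- function(map) {
  v <- map$visited
  P <- map$occupancy_s[v] / sum(map$occupancy_s[v])
  R <- map$rate[v]
  denom <- sum(P * R^2)
  if (!is.finite(denom) || denom <= 0)
    stop("spatial sparsity undefined: map has no activity")
  sum(P * R)^2 / denom
}

#' Within-session spatial stability
#'
#' Splits the epoch at its temporal midpoint, builds a rate map from each
#' half with identical binning, and returns Pearson's correlation between
#' smoothed rates of bins visited in both halves.
#'
#' @param spike_times Spike times (s).
#' @param track Position track covering the epoch.
#' @param bin_cm Bin side (cm).
#' @return Correlation coefficient; warns when fewer than 10 shared
#'   visited bins are available.
#' @export
split_half_correlation <- function(spike_times, track, bin_cm = 5) {
  tmid <- (min(track$time_s) + max(track$time_s)) / 2
  a <- track[track$time_s < tmid, , drop = FALSE]
  b <- track[track$time_s >= tmid, , drop = FALSE]
  # both halves on the full-epoch grid so bins correspond
  bounds <- list(x0 = min(track$x_cm), y0 = min(track$y_cm),
                 nx = max(1L, ceiling(diff(range(track$x_cm)) / bin_cm + 1e-9)),
                 ny = max(1L, ceiling(diff(range(track$y_cm)) / bin_cm + 1e-9)))
  ma <- build_rate_map(spike_times[spike_times < tmid],
                       map_context(a, bin_cm, bounds = bounds))
  mb <- build_rate_map(spike_times[spike_times >= tmid],
                       map_context(b, bin_cm, bounds = bounds))
  common <- which(ma$visited & mb$visited)
  if (length(common) < 10)
    warning("fewer than 10 bins visited in both halves; correlation unstable")
  ra <- ma$rate[common]; rb <- mb$rate[common]
  if (length(common) < 2 || stats::sd(ra) == 0 || stats::sd(rb) == 0)
    return(NA_real_)
  stats::cor(ra, rb)
}

#' Proportion of active units
#'
#' A unit is active when at least one of its rate maps has a peak rate
#' exceeding the threshold.
#'
#' @param peak_rates List (one element per unit) of numeric vectors of
#'   map peak rates (Hz), or a numeric vector with one peak per unit.
#' @param threshold_hz Activity threshold (default 2 Hz).
#' @return Fraction of units active.
#' @export
active_proportion <- function(peak_rates, threshold_hz = 2) {
  if (is.numeric(peak_rates)) peak_rates <- as.list(peak_rates)
  if (!length(peak_rates)) stop("no units supplied")
  mean(vapply(peak_rates, function(p) any(p > threshold_hz, na.rm = TRUE),
              logical(1)))
}

# nearest index in sorted vector `grid` for each value of `x`
nearest_index <- function(grid, x) {
  i <- findInterval(x, grid, all.inside = TRUE)
  lo <- abs(x - grid[i]); hi <- abs(grid[pmin(i + 1L, length(grid))] - x)
  ifelse(hi < lo, pmin(i + 1L, length(grid)), i)
}
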