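test_that("the rate-map smoothing kernel sums to one", {
  k <- rate_map_kernel()
  expect_equal(dim(k), c(5L, 5L))
  expect_equal(sum(k), 1.0)
  expect_equal(k[3, 3], 0.16)
  expect_identical(k, t(k))
})

test_that("speed computation matches analytic trajectories", {
  tr <- data.frame(time_s = seq(0, 10, by = 1 / 30),
                   x_cm = 0, y_cm = 0)
  expect_true(all(compute_speed(tr) == 0))
  tr2 <- data.frame(time_s = seq(0, 10, by = 1 / 30))
  tr2$x_cm <- 10 * tr2$time_s; tr2$y_cm <- 0
  sp <- compute_speed(tr2)
  mid <- sp[20:280]
  expect_lt(max(abs(mid - 10)), 0.5)
})

test_that("rate maps conserve spikes and occupancy and apply visit rules", {
  tr <- forage_track()
  ctx <- forage_context()
  # occupancy sums to the tracked duration
  expect_equal(sum(ctx$occupancy_s), nrow(tr) * median(diff(tr$time_s)),
               tolerance = 1e-6)
  set.seed(14)
  st <- sort(sample(tr$time_s, 500)) + runif(500, -0.01, 0.01)
  map <- build_rate_map(st, ctx)
  expect_equal(sum(map$counts), 500)
  # all spikes at one location: raw argmax in that bin
  one <- rep(tr$time_s[1000], 50)
  m1 <- build_rate_map(one, ctx)
  b <- which.max(ifelse(is.na(m1$raw), -1, m1$raw))
  expect_equal(m1$counts[b], 50)
  # a bin occupied for only 100 ms is unvisited
  tr_small <- data.frame(time_s = seq(0, 1, by = 1 / 30))
  tr_small$x_cm <- c(rep(2.5, 3), seq(10, 60, length.out = 28))
  tr_small$y_cm <- 2.5
  ctx_small <- map_context(tr_small)
  first_bin <- ctx_small$sample_bin[1]
  expect_lt(ctx_small$occupancy_s[first_bin], 0.15)
  expect_false(ctx_small$visited[first_bin])
})

test_that("smoothing preserves the mean rate over interior regions", {
  # uniform rate on a fully visited grid stays uniform after smoothing
  tr <- forage_track()
  ctx <- forage_context()
  vb <- which(ctx$visited)
  uni <- rep(1, length(vb))
  sm <- as.numeric(ctx$smooth %*% uni)
  expect_lt(max(abs(sm - 1)), 1e-9)        # renormalised kernel: exact
})

test_that("spatial information matches hand-evaluated maps", {
  # uniform map -> 0 bits
  u <- rate_map(matrix(2, 4, 4), matrix(1, 4, 4))
  expect_equal(spatial_information(u), 0)
  # two equal-occupancy bins, rates (2, 0) -> 1 bit
  m2 <- rate_map(matrix(c(2, 0), 1), matrix(c(1, 1), 1))
  expect_equal(spatial_information(m2), 1.0)
  # four equal-occupancy bins, rates (4,0,0,0) -> 2 bits
  m4 <- rate_map(matrix(c(4, 0, 0, 0), 1), matrix(1, 1, 4))
  expect_equal(spatial_information(m4), 2.0)
  # invariance under uniform rescaling of rates
  m4b <- rate_map(matrix(c(40, 0, 0, 0), 1), matrix(1, 1, 4))
  expect_equal(spatial_information(m4b), spatial_information(m4))
  expect_error(spatial_information(rate_map(matrix(0, 2, 2),
                                            matrix(1, 2, 2))),
               "undefined")
})

test_that("spatial sparsity matches hand-evaluated maps", {
  expect_equal(spatial_sparsity(rate_map(matrix(3, 5, 5),
                                         matrix(1, 5, 5))), 1.0)
  m <- rate_map(matrix(c(4, 0, 0, 0), 1), matrix(1, 1, 4))
  expect_equal(spatial_sparsity(m), 0.25)
  expect_error(spatial_sparsity(rate_map(matrix(0, 2, 2),
                                         matrix(1, 2, 2))), "undefined")
})

test_that("field width drives information down and sparsity up", {
  spec0 <- forage_spec()
  tr <- forage_track()
  ctx <- forage_context()
  res <- vapply(c(5, 10, 20), function(w) {
    spec <- session_spec(epochs = spec0$epochs, n_units = 1,
                         field_width_cm = w, peak_rate_hz = 8,
                         baseline_rate_hz = 0.1)
    sp <- synthesize_spikes(spec, no_events(), tr, seed = 15L)
    map <- build_rate_map(sp$spikes$time_s, ctx)
    c(spatial_information(map), spatial_sparsity(map))
  }, numeric(2))
  expect_true(all(diff(res[1, ]) < 0))   # information decreases
  expect_true(all(diff(res[2, ]) > 0))   # sparsity increases
})

test_that("split-half stability separates stable cells from noise", {
  tr <- forage_track()
  # deterministic periodic spiking at a fixed location visit pattern:
  # a stable synthetic place cell
  spec <- session_spec(epochs = forage_spec()$epochs, n_units = 1,
                       field_width_cm = 12, peak_rate_hz = 10,
                       baseline_rate_hz = 0.2)
  sp <- synthesize_spikes(spec, no_events(), tr, seed = 16L)
  r_stable <- split_half_correlation(sp$spikes$time_s, tr)
  expect_gt(r_stable, 0.7)
  # spatially unstructured Poisson spiking: near-zero expected r
  set.seed(17)
  rs <- replicate(30, {
    st <- sort(runif(600, 0, 600))
    split_half_correlation(st, tr)
  })
  expect_lt(abs(mean(rs)), 0.1)
})

test_that("active proportion counts units by peak-rate threshold", {
  expect_equal(active_proportion(c(1, 3, 5), threshold_hz = 2), 2 / 3)
  expect_equal(active_proportion(rep(0, 5)), 0)
  peaks <- c(rep(3, 30), rep(0.5, 5))
  expect_equal(active_proportion(peaks), 30 / 35)
  expect_equal(active_proportion(peaks, threshold_hz = Inf), 0)
  expect_error(active_proportion(list()), "no units")
})
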