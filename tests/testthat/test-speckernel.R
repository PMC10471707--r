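test_that("kernels recover a planted single-LED filter", {
  nz <- build_spectral_noise(seed = 5)
  cell <- gt_cell("r", baseline_rate = 1, gain = 60, on_weight = 1,
                  off_weight = 0, filter_kind = "biphasic", tau_s = 0.03,
                  spectral_weights = c(1, 0, 0, 0, 0, 0))
  sp <- simulate_lnp(list(cell), nz, seed = 2, dt = 0.002)
  expect_gt(nrow(sp), 5000)
  ks <- compute_kernel(sp$time_s, nz)
  expect_length(ks$time, 51)
  # ground-truth filter, time-reversed onto the pre-spike axis with latency
  k_true <- lnp_filter("biphasic", 0.03, 0.02)
  lag <- -ks$time - cell$latency_s
  k_grid <- approx(seq(0, by = 0.02, length.out = length(k_true)), k_true,
                   xout = pmax(0, lag), rule = 2)$y
  k_grid[lag < 0] <- 0
  expect_gt(cor(ks$raw["R", ], k_grid), 0.9)
  # non-driven LEDs stay within the null band
  expect_lt(max(abs(ks$z[c("G", "C", "B"), ])), 4)
})

test_that("stimulus-independent spiking yields flat z-kernels", {
  nz <- build_spectral_noise(seed = 15, n_frames = 9000)
  set.seed(16)
  sp <- sort(runif(10000, 0, 450))
  ks <- compute_kernel(sp, nz)
  expect_lt(max(abs(ks$z), na.rm = TRUE), 4)
})

test_that("kernel estimates sharpen with spike count", {
  nz <- build_spectral_noise(seed = 5)
  cell <- gt_cell("r", baseline_rate = 1, gain = 60, on_weight = 1,
                  off_weight = 0, filter_kind = "biphasic", tau_s = 0.03,
                  spectral_weights = c(1, 0, 0, 0, 0, 0))
  sp <- simulate_lnp(list(cell), nz, seed = 2, dt = 0.002)$time_s
  k_true <- lnp_filter("biphasic", 0.03, 0.02)
  cors <- sapply(c(100, 500, length(sp)), function(n) {
    ks <- compute_kernel(sp[seq_len(n)], nz)
    lag <- -ks$time - 0.1
    kg <- approx(seq(0, by = 0.02, length.out = length(k_true)), k_true,
                 xout = pmax(0, lag), rule = 2)$y
    kg[lag < 0] <- 0
    cor(ks$raw["R", ], kg)
  })
  expect_true(all(diff(cors) > -0.01))
  expect_gt(cors[3], cors[1] + 0.05)
})

test_that("kernel amplitude is the z-range with the 2.5 discard rule", {
  flat <- matrix(0, 4, 51, dimnames = list(c("R", "G", "C", "B"), NULL))
  expect_equal(kernel_amplitude(flat)$max_amplitude, 0)
  k <- flat
  k[2, 10] <- 3; k[2, 30] <- -2
  res <- kernel_amplitude(k)
  expect_equal(unname(res$per_led["G"]), 5)
  expect_false(res$discarded)
  weak <- flat; weak[1, 5] <- 2.4
  expect_true(kernel_amplitude(weak)$discarded)
})

test_that("spectral centroid locates the dominant frequency", {
  t <- seq(0, 1, by = 0.02)
  res_hz <- 50 / 256
  pure <- sin(2 * pi * 5 * t)
  expect_equal(spectral_centroid(pure), 5, tolerance = res_hz / 2 / 5 + 0.02)
  mix <- sin(2 * pi * 2 * t) + sin(2 * pi * 8 * t)
  expect_equal(spectral_centroid(mix), 5, tolerance = 0.1)
  expect_equal(spectral_centroid(10 * pure), spectral_centroid(pure))
  expect_true(is.na(spectral_centroid(rep(1, 51))))
  # the literal reciprocal-weighted reading is available behind the flag
  expect_lt(spectral_centroid(pure, convention = "reciprocal"), 1)
})

test_that("opponency classification follows sign agreement above threshold", {
  mk <- function(v) matrix(v, ncol = 1)
  expect_equal(classify_opponency(mk(c(4, 4, 4, -4)), 3)$labels, 1)
  expect_equal(classify_opponency(mk(c(4, 4, 4, 4)), 3)$labels, 0)
  expect_true(is.na(classify_opponency(mk(c(2, -2, 1, 0)), 3)$labels))
  # invariant to a simultaneous sign flip of all four kernels
  set.seed(17)
  zk <- matrix(rnorm(4 * 100, sd = 3), 4)
  expect_identical(classify_opponency(zk, 3)$labels,
                   classify_opponency(-zk, 3)$labels)
})

test_that("the colour opponency index needs 20 opponent bins and kernel QI", {
  lab_full <- rep(1, 100)
  p <- structure(list(labels = lab_full, amp_threshold = 3),
                 class = "opponency_profile")
  expect_equal(colour_opponency_index(p, kernel_qi = 2000), 1)
  half <- structure(list(labels = c(rep(1, 50), rep(0, 50))),
                    class = "opponency_profile")
  expect_equal(colour_opponency_index(half, kernel_qi = 2000), 0.5)
  few <- structure(list(labels = c(rep(1, 19), rep(0, 981))),
                   class = "opponency_profile")
  expect_true(is.na(colour_opponency_index(few, kernel_qi = 2000)))
  expect_true(is.na(colour_opponency_index(p, kernel_qi = 999)))
})

test_that("time-normalised opponency rescales onset to -1 and spike to 0", {
  zk <- matrix(0, 4, 500)
  zk[1, 100:500] <- seq(1, 6, length.out = 401)
  zk[4, 100:500] <- -seq(1, 6, length.out = 401)
  prof <- classify_opponency(zk, 3)
  tn <- time_normalised_opponency(prof, zk)
  expect_equal(tn$time[1], -1)
  expect_equal(tn$time[length(tn$time)], 0)
  vals <- tn$values[!is.na(tn$values)]
  expect_true(all(vals %in% c(-1, 1)))
  # all-opponent profile maps to constant +1 over its responsive span
  expect_true(all(tail(vals, 100) == 1))
  # no onset: flagged
  quiet <- matrix(0.1, 4, 100)
  pq <- classify_opponency(quiet, 3)
  expect_warning(res <- time_normalised_opponency(pq, quiet), "onset")
  expect_null(res)
})

test_that("opponent-early profiles convert non-opponent tails to -1", {
  lab <- c(rep(NA, 50), rep(1, 300), rep(0, 150))
  prof <- structure(list(labels = lab), class = "opponency_profile")
  zk <- matrix(0, 4, 500)
  zk[1, 51:500] <- 5
  tn <- time_normalised_opponency(prof, zk)
  v <- tn$values[!is.na(tn$values)]
  expect_equal(v[1], 1)
  expect_equal(v[length(v)], -1)
})
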