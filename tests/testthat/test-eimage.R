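test_that("an EI over a single snippet equals that snippet", {
  ax <- synthetic_axon(c(15, 15), matrix(c(15, 40), ncol = 2))
  src <- simulate_footprint(ax, n_spikes = 1, noise_sd = 0)
  ei <- compute_ei(src)
  expect_equal(dim(ei$stas), c(4096, 50))
  expect_equal(ei$stas, src$template)
  expect_equal(ei$n_spikes, 1)
})

test_that("spikes outside the first half hour are excluded from the EI", {
  ax <- synthetic_axon(c(15, 15), NULL)
  src <- simulate_footprint(ax, n_spikes = 4, noise_sd = 0)
  ei <- compute_ei(src, spikes = c(10, 20, 2000, 3000))
  expect_equal(ei$n_spikes, 2)
  expect_error(compute_ei(src, spikes = rep(5000, 4)), "no usable spikes")
})

test_that("a flat-zero EI yields an empty, non-rejected mask", {
  ei <- structure(list(stas = matrix(0, 4096, 50), n_spikes = 1,
                       sampling_rate = 18000), class = "electrical_image")
  es <- compute_esignal(ei)
  expect_false(es$rejected)
  expect_equal(sum(es$mask), 0)
})

test_that("a single biphasic channel and its neighbours are retained", {
  stas <- matrix(rnorm(4096 * 50, sd = 0.5), 4096, 50)
  w <- spike_waveform() * 80
  for (ch in c((20 - 1) * 64 + 20, (20 - 1) * 64 + 21)) {
    stas[ch, ] <- stas[ch, ] + w
  }
  ei <- structure(list(stas = stas, n_spikes = 100, sampling_rate = 18000),
                  class = "electrical_image")
  es <- compute_esignal(ei)
  expect_true(es$mask[20, 20])
  expect_true(es$mask[20, 21])
  expect_false(es$rejected)
})

test_that("maps with more than 400 surviving channels are rejected", {
  stas <- matrix(0, 4096, 50)
  w <- spike_waveform() * 100
  # a 21x21 block of waveform channels (441 survivors)
  for (r in 20:40) for (cc in 20:40) {
    stas[(r - 1) * 64 + cc, ] <- w
  }
  ei <- structure(list(stas = stas, n_spikes = 10, sampling_rate = 18000),
                  class = "electrical_image")
  es <- compute_esignal(ei)
  expect_true(es$rejected)
  expect_error(trace_axon(ei, es), "rejected")
})

test_that("a straight synthetic axon is traced at the constructed length", {
  ax <- synthetic_axon(c(10, 10), matrix(c(10, 45), ncol = 2),
                       velocity_m_s = 1)
  src <- simulate_footprint(ax, n_spikes = 1, noise_sd = 0)
  ei <- compute_ei(src)
  tr <- trace_axon(ei, compute_esignal(ei))
  expect_true(tr$detected)
  # the path runs straight from the origin to the terminal 35 channels out
  expect_equal(tr$d_short_mm, 35 * 0.042, tolerance = 0.05)
  # transit time consistent with arclength / velocity
  expect_equal(tr$fmin_max, max(ax$path$delay_frames), tolerance = 0.08)
})

test_that("fractionated footprints stay connected at graph radius 2.2", {
  # axon with every second channel missing (saltatory footprint)
  ax <- synthetic_axon(c(10, 10), matrix(c(10, 44), ncol = 2),
                       velocity_m_s = 1)
  src <- simulate_footprint(ax, n_spikes = 1, noise_sd = 0)
  ei <- compute_ei(src)
  gapped <- ei
  cols <- seq(18, 44, by = 3)
  gapped$stas[(10 - 1) * 64 + cols, ] <- 0
  es <- compute_esignal(gapped)
  tr <- trace_axon(gapped, es, graph_radius = 2.2, min_path_channels = 5)
  expect_true(tr$detected)
  # structural validity: consecutive path channels within the graph radius
  steps <- sqrt(diff(tr$path$row)^2 + diff(tr$path$col)^2)
  expect_true(all(steps <= 2.2))
})

test_that("conduction velocity follows the transit-time formula", {
  mk <- function(d, f) structure(list(d_short_mm = d, fmin_max = f,
                                      detected = TRUE), class = "axon_trace")
  expect_equal(conduction_velocity(mk(1.5, 27), 18000), 1.0)
  expect_equal(conduction_velocity(mk(0, 27), 18000), 0)
  expect_error(conduction_velocity(mk(1.5, 0), 18000), "undefined")
  expect_error(conduction_velocity(structure(list(detected = FALSE),
                                             class = "axon_trace")),
               "not detected")
})

test_that("velocity recovery is scale-consistent", {
  trace_at <- function(v) {
    ax <- synthetic_axon(c(10, 10), matrix(c(10, 45), ncol = 2),
                         velocity_m_s = v)
    src <- simulate_footprint(ax, n_spikes = 1, noise_sd = 0)
    ei <- compute_ei(src)
    trace_axon(ei, compute_esignal(ei))
  }
  t1 <- trace_at(1)
  t2 <- trace_at(2)
  expect_lte(abs(t2$fmin_max - t1$fmin_max / 2), 1)
  expect_equal(conduction_velocity(t1), 1, tolerance = 0.05)
  expect_equal(conduction_velocity(t2), 2, tolerance = 0.05)
})

test_that("the detection asymptote fit recovers a saturating curve", {
  # constant detection fraction
  flat <- fit_axon_detection_asymptote(rep(c(100, 1000, 5000, 9000), each = 50),
                                       rep(c(TRUE, FALSE), 100))
  expect_equal(flat$asymptote, 0.5, tolerance = 0.02)
  # binomial draws around A (1 - exp(-n/k)), A = 0.87, k = 2000
  set.seed(31)
  n <- round(exp(runif(3000, log(100), log(20000))))
  p <- 0.87 * (1 - exp(-n / 2000))
  det <- runif(3000) < p
  fit <- fit_axon_detection_asymptote(n, det, n_bins = 10)
  expect_true(fit$fit_ok)
  expect_equal(fit$asymptote, 0.87, tolerance = 0.06)
  # saturating property: asymptote at least the top observed fraction - 0.02
  expect_gte(fit$asymptote, max(fit$bins$fraction) - 0.02)
})
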