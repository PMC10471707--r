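test_that("chirp spectrum finds a planted line and stays non-negative", {
  t <- seq(0, 30, by = 1 / 200)
  x <- sin(2 * pi * 10 * t)
  sp <- chirp_spectrum(x, 200)
  expect_equal(sp$best_frequency, 10, tolerance = 0.01)
  expect_true(all(sp$power >= 0))
  expect_equal(sum(sp$power_norm), 1)
  expect_warning(flat <- chirp_spectrum(rep(2, 100)), "flat")
  expect_true(flat$flat)
})

test_that("white-noise traces give an approximately flat spectrum", {
  # for ~4096 independent periodogram bins the max/mean ratio concentrates
  # near log(n) ~ 8.3; a line spectrum would give ratios in the thousands
  set.seed(18)
  mx <- replicate(10, {
    sp <- chirp_spectrum(rnorm(6000), 200)
    max(sp$power_norm) / mean(sp$power_norm)
  })
  expect_lt(max(mx), 16)
})

test_that("high-frequency index follows its power contrast", {
  mk <- function(freq, power) {
    structure(list(frequency = freq, power = power, flat = FALSE),
              class = "chirp_spectrum")
  }
  freq <- seq(0.1, 20, by = 0.1)
  expect_equal(high_frequency_index(mk(freq, rep(1, length(freq)))), 0)
  hi_only <- ifelse(freq >= 4 & freq <= 15, 1, 0)
  expect_equal(high_frequency_index(mk(freq, hi_only)), 1)
  spec <- mk(c(1, 5), c(3, 1))  # P_low = 3, P_high = 1
  expect_equal(high_frequency_index(spec), -0.5)
  expect_equal(high_frequency_index(spec, invert_windows = TRUE), 0.5)
  # antisymmetry under window exchange
  set.seed(19)
  pw <- runif(length(freq))
  expect_equal(high_frequency_index(mk(freq, pw)),
               -high_frequency_index(mk(freq, pw), invert_windows = TRUE))
})

test_that("the responsiveness rule needs 20% extra spikes", {
  expect_true(chirp_responsive(72, 10))   # expected 60, needs >= 72
  expect_false(chirp_responsive(71, 10))
  expect_true(chirp_responsive(1, 0))
})

test_that("phase angles map On and Off onsets to 0 and pi", {
  # On onsets: phase multiples of 2 pi; invert the phase map numerically
  phi_targets <- 2 * pi * c(3, 10, 40)
  t_on <- sapply(phi_targets, function(p) {
    uniroot(function(t) chirp_phase(t) - p, c(0.01, 29.9), tol = 1e-12)$root
  })
  ph <- phase_angles(t_on + 0.1, shift_s = 0.1)
  th <- unlist(ph)
  expect_equal(unname(pmin(th, 2 * pi - th)), rep(0, 3), tolerance = 1e-6)
  t_off <- sapply(phi_targets + pi, function(p) {
    uniroot(function(t) chirp_phase(t) - p, c(0.01, 29.9), tol = 1e-12)$root
  })
  ph_off <- phase_angles(t_off + 0.1, shift_s = 0.1)
  expect_equal(unlist(ph_off), rep(pi, 3), tolerance = 1e-6)
  # spikes shifted before the chirp start are dropped
  expect_equal(sum(lengths(phase_angles(0.05, shift_s = 0.1))), 0)
})

test_that("vector strength matches closed-form cases and the Rayleigh null", {
  expect_equal(vector_strength(rep(1.3, 50)), 1)
  expect_equal(vector_strength(c(0.2, 0.2 + pi)), 0, tolerance = 1e-12)
  expect_true(is.na(vector_strength(numeric(0))))
  # rotation invariance
  set.seed(20)
  th <- runif(200, 0, 2 * pi)
  expect_equal(vector_strength(th + 0.9), vector_strength(th))
  # E[r] for n uniform phases ~ sqrt(pi)/2 / sqrt(n)
  rs <- replicate(400, vector_strength(runif(100, 0, 2 * pi)))
  expect_equal(mean(rs), sqrt(pi) / 2 / sqrt(100), tolerance = 0.1)
})

test_that("the Poisson bootstrap null is calibrated near 5%", {
  set.seed(22)
  n_cells <- 250
  flags <- logical(n_cells)
  for (i in seq_len(n_cells)) {
    n <- rpois(1, 40)
    r <- vector_strength(runif(n, 0, 2 * pi))
    flags[i] <- bootstrap_null(40, r, n_boot = 400, seed = i)$significant
  }
  expect_gt(mean(flags), 0.03)
  expect_lt(mean(flags), 0.07)
})

test_that("locked cells are significant; zero-count bins never are", {
  res <- bootstrap_null(c(100, 0), c(1, NA), n_boot = 300, seed = 2)
  expect_true(res$significant[1])
  expect_false(res$significant[2])
  expect_true(is.na(res$r_reported[2]))
  # shift choice does not matter for Poisson spikes
  set.seed(23)
  sp <- sort(runif(600, 0, 30))
  r0 <- vapply(phase_angles(sp, shift_s = 0), vector_strength, numeric(1))
  r1 <- vapply(phase_angles(sp, shift_s = 0.1), vector_strength, numeric(1))
  expect_lt(abs(mean(r0, na.rm = TRUE) - mean(r1, na.rm = TRUE)), 0.05)
})

test_that("bin centre frequencies follow the exponential sweep", {
  cf <- chirp_bin_centres()
  expect_length(cf, 10)
  expect_true(all(diff(cf) > 0))
  expect_gt(cf[1], 1); expect_lt(cf[10], 30)
  # time-average of f over the full sweep equals the single-bin centre
  expect_equal(chirp_bin_centres(n_bins = 1), 29 / log(30), tolerance = 1e-9)
})
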