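test_that("KDE rate traces integrate to one and are translation equivariant", {
  single <- kde_rate(2.0, 4)
  expect_equal(single$time[which.max(single$rate)], 2.0, tolerance = 0.01)
  expect_equal(single$integral, 1, tolerance = 0.01)
  set.seed(10)
  sp <- runif(2000, 1, 3)
  a <- kde_rate(sp, 6)
  b <- kde_rate(sp + 0.5, 6)
  step <- a$time[2] - a$time[1]
  shift_idx <- round(0.5 / step)
  interior <- 150:500
  expect_equal(b$rate[interior + shift_idx], a$rate[interior],
               tolerance = 0.02)
  # uniform spikes: interior density flat
  set.seed(11)
  u <- kde_rate(runif(10000, 0, 4), 4)
  inner <- u$rate[u$time > 0.4 & u$time < 3.6]
  expect_lt(max(inner) / min(inner), 1.25)
  empty <- kde_rate(numeric(0), 4)
  expect_true(all(empty$rate == 0))
})

test_that("response amplitudes separate transient and sustained energy", {
  tl <- build_white_steps(contrasts = 1)
  # burst at 100 ms after the On transition, repeated over 5 sweeps
  burst <- as.vector(sapply(0:4, function(r) r * 4 + runif(30, 0.09, 0.13)))
  amp <- response_amplitudes(burst, tl, 5)
  on_row <- amp[amp$kind == "WS_on", ]
  expect_gt(on_row$a_tr, on_row$a_sus)
  expect_equal(on_row$a_mean, 30)  # 30 burst spikes per repeat
  off_row <- amp[amp$kind == "WS_off", ]
  expect_equal(off_row$a_mean, 0)
  expect_equal(off_row$a_tr, 0)
  # near-constant rate: the two windows roughly agree
  set.seed(12)
  dense <- as.vector(sapply(0:4, function(r) r * 4 + sort(runif(600, 0, 2))))
  amp2 <- response_amplitudes(dense, tl, 5)
  on2 <- amp2[amp2$kind == "WS_on", ]
  expect_equal(on2$a_tr, on2$a_sus, tolerance = 0.35)
})

test_that("baseline is the amplitude-histogram mode with low tie-break", {
  expect_equal(estimate_baseline(rep(2.5, 100)), 2.5)
  trace <- c(rep(1, 900), rep(10, 100))
  expect_equal(estimate_baseline(trace), 1, tolerance = 0.01)
  tie <- c(rep(1, 500), rep(9, 500))
  expect_lt(estimate_baseline(tie), 2)
})

test_that("polarity, transience and dominance indices follow their contrasts", {
  expect_equal(polarity_index(2, 0), 1)
  expect_equal(polarity_index(1, 1), 0)
  expect_equal(polarity_index(3, 1), 0.5)
  expect_equal(transience_index(5, 0), 1)
  expect_equal(transience_index(5, 5), 0)
  expect_equal(transience_index(1, 3), -0.5)
  expect_equal(spectral_dominance(1, 0), 1)
  expect_equal(spectral_dominance(2, 2), 0)
  expect_equal(spectral_dominance(1, 3), -0.5)
  # antisymmetry and scale invariance
  for (ab in list(c(2, 5), c(0.3, 0.1), c(7, 7))) {
    expect_equal(polarity_index(ab[1], ab[2]), -polarity_index(ab[2], ab[1]))
    expect_equal(polarity_index(10 * ab[1], 10 * ab[2]),
                 polarity_index(ab[1], ab[2]))
  }
  expect_warning(expect_true(is.nan(polarity_index(0, 0))), "undefined")
  expect_equal(compound_ti(0.8, -0.2, 0.5), 0.8)
  expect_equal(compound_ti(0.8, -0.2, -0.5), -0.2)
})

test_that("opsin templates map the 10%-of-maximum point to zero", {
  lmax <- 508
  grid <- seq(350, 700, by = 1)
  tmpl <- opsin_template(lmax, grid)
  expect_equal(opsin_template(lmax, lmax), 1, tolerance = 1e-3)
  s <- pigment_nomogram(grid, lmax)
  at10 <- grid[which.min(abs(s - 0.1))]
  expect_equal(opsin_template(lmax, at10), 0, tolerance = 0.02)
  # 1% sensitivity clips to exactly zero
  at1 <- grid[which.min(abs(s - 0.01))]
  expect_equal(opsin_template(lmax, at1), 0)
  expect_true(all(tmpl >= 0 & tmpl <= 1 + 1e-9))
})

test_that("spectral tuning index measures width against the best template", {
  wl <- led_specs()$wavelength_nm
  tmpl <- opsin_template(571, wl)
  res <- spectral_tuning_index(tmpl, peak_spikes = 10)
  expect_equal(res$st, 0, tolerance = 1e-9)
  expect_equal(res$best_class, "LWS")
  # narrower than the opsin: response only at its peak wavelength
  narrow <- ifelse(tmpl == max(tmpl), tmpl, 0)
  expect_gt(spectral_tuning_index(narrow, peak_spikes = 10)$st, 0)
  # flat tuning: broader than any template
  expect_lt(spectral_tuning_index(rep(1, 6), peak_spikes = 10)$st, 0)
  # minimum response threshold
  expect_true(is.na(spectral_tuning_index(tmpl, peak_spikes = 2)$st))
})

test_that("latency is the time to half the post-transition peak", {
  t <- seq(0, 2, by = 0.005)
  ramp <- pmin(1, pmax(0, (t - 0.06) / 0.12))  # half peak at 120 ms
  expect_equal(response_latency(t, ramp, 0, smooth_s = 0), 0.12,
               tolerance = 0.01)
  # a step smoothed by the 40 ms box crosses half peak near the step
  stepr <- as.numeric(t >= 0.5)
  lat <- response_latency(t, stepr, 0.5, smooth_s = 0.04)
  expect_lt(abs(lat), 0.025)
  expect_warning(res <- response_latency(t, rep(0, length(t)), 0), "no positive")
  expect_true(is.na(res))
})

test_that("step PCA zeroes leading bins and captures planted envelopes", {
  set.seed(13)
  env1 <- sin(seq(0, pi, length.out = 50))
  env2 <- exp(-seq(0, 5, length.out = 50))
  resp <- sapply(1:10, function(i) runif(1, 0.5, 2) * env1 +
                   runif(1, -1, 1) * env2)
  pc <- step_pca(resp)
  expect_gt(sum(pc$var_explained), 0.99)
  expect_equal(dim(pc$components), c(50, 2))
  # components oriented positive at their largest magnitude, loadings peak 1
  for (j in 1:2) {
    expect_gt(pc$components[which.max(abs(pc$components[, j])), j], 0)
    expect_equal(max(abs(pc$loadings[, j])), 1)
  }
  # rank-1 input: second component negligible
  r1 <- sapply(1:10, function(i) i * env1)
  expect_warning(pcr1 <- step_pca(r1), "rank")
  expect_lt(pcr1$var_explained[2], 1e-6)
})

test_that("external traces harmonise through deconvolution and cropping", {
  dt <- 0.02
  t <- seq(0, 12, by = dt)
  rate <- rep(0, length(t))
  on_tr <- c(2, 6, 10)
  for (t0 in on_tr) rate[t >= t0 & t < t0 + 0.3] <- 5  # purely transient On
  # calcium-like convolution with a 0.4 s decaying kernel
  kern <- exp(-seq(0, 2, by = dt) / 0.4)
  ca <- conv_causal(rate, kern)
  dec <- harmonise_external(t, ca, on_tr, on_tr + 1, deconv_tau_s = 0.4)
  raw <- harmonise_external(t, rate, on_tr, on_tr + 1)
  expect_gt(cor(dec$on_trace, raw$on_trace), 0.95)
  expect_equal(dec$pi, 1, tolerance = 0.05)
  # purely transient response: 1 s and 2 s windows give identical PI
  wide <- harmonise_external(t, rate, on_tr, on_tr + 1, window_s = 2)
  expect_equal(raw$pi, wide$pi, tolerance = 1e-6)
  # 6:1 polarity ratio: On included, Off excluded
  rate_onoff <- rate
  for (t0 in on_tr + 1) rate_onoff[t >= t0 & t < t0 + 0.3] <- 5 / 6
  h <- harmonise_external(t, rate_onoff, on_tr, on_tr + 1)
  expect_true(h$include_on)
  expect_false(h$include_off)
})
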