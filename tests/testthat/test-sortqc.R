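test_that("rate exclusion keeps the 10 Hz boundary", {
  expect_true(rate_exclusion(seq_len(36000) / 10, 3600))
  expect_false(rate_exclusion(seq_len(36001) / 10, 3600))
  expect_true(rate_exclusion(numeric(0), 3600))
})

test_that("circularity is 1 for isotropic clouds and large for lines", {
  set.seed(3)
  cloud <- matrix(rnorm(20000), ncol = 2)
  expect_equal(circularity_index(cloud), 1, tolerance = 0.05)
  line <- cbind(1:100, 2 * (1:100) + rnorm(100, sd = 1e-3))
  expect_gt(circularity_index(line), 2)
  expect_gte(circularity_index(matrix(rnorm(40), ncol = 2)), 1)
  expect_identical(circularity_index(cbind(1:10, 2 * (1:10))), Inf)
  # rotation invariance
  th <- 0.7
  rot <- cloud %*% matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  expect_equal(circularity_index(rot), circularity_index(cloud),
               tolerance = 1e-6)
})

test_that("waveform similarity separates single and merged units", {
  set.seed(4)
  tmpl <- sin(seq(0, 2 * pi, length.out = 30))
  single <- t(replicate(300, tmpl + rnorm(30, sd = 0.3)))
  res1 <- waveform_similarity(single, n_boot = 200, seed = 1)
  expect_gt(res1$p_value, 0.1)
  merged <- rbind(
    t(replicate(150, tmpl + rnorm(30, sd = 0.1))),
    t(replicate(150, -tmpl + rnorm(30, sd = 0.1)))
  )
  res2 <- waveform_similarity(merged, n_boot = 200, seed = 1)
  expect_lt(res2$p_value, 0.01)
  const <- matrix(1, 20, 30)
  expect_equal(waveform_similarity(const)$p_value, 1)
})

test_that("On/Off independence flags a constructed dependent unit", {
  set.seed(5)
  # dependent: On spikes only in the low-loading mode
  loadings <- c(rnorm(500, -4), rnorm(500, 4))
  labels <- rep(c("On", "Off"), each = 500)
  dep <- onoff_independence(labels, loadings, seed = 2)
  expect_lt(dep$p_value, 1e-6)
  # a Bonferroni screen at alpha = 0.05 / 2000 still flags it
  expect_lt(dep$p_value, 0.05 / 2000)
  # independent labels: p should not be extreme (single-draw sanity check)
  ind <- onoff_independence(sample(labels), loadings, seed = 2)
  expect_gt(ind$p_value, 1e-4)
  expect_error(onoff_independence(rep("On", 10), rnorm(10)), "both")
})

test_that("SNR quality index calibrates against repeat structure", {
  tmpl <- sin(seq(0, 4 * pi, length.out = 500))
  ident <- replicate(5, tmpl)
  expect_equal(snr_quality_index(ident), 1)
  set.seed(6)
  noise <- matrix(rnorm(5000), ncol = 5)
  expect_equal(snr_quality_index(noise), 1 / 5, tolerance = 0.2 * (1 / 5) * 5)
  # invariance to offset and positive rescaling
  C <- replicate(4, tmpl + rnorm(500, sd = 0.5))
  expect_equal(snr_quality_index(C + 7), snr_quality_index(C))
  expect_equal(snr_quality_index(3.2 * C), snr_quality_index(C))
  expect_true(is.nan(snr_quality_index(matrix(1, 10, 3))))
})

test_that("white-noise repeats give SNR QI near 1/R", {
  set.seed(61)
  qis <- replicate(30, snr_quality_index(matrix(rnorm(1000 * 5), ncol = 5)))
  expect_equal(mean(qis), 1 / 5, tolerance = 0.2)
})

test_that("step quality index rewards repeatable, modulated responses", {
  set.seed(7)
  burst <- function() sort(c(runif(20, 1, 1.3), runif(5, 0, 4)))
  trains <- replicate(5, burst(), simplify = FALSE)
  qi_locked <- step_quality_index(trains, 0, 4)
  shuffled <- lapply(trains, function(s) sort(runif(length(s), 0, 4)))
  qi_shuf <- step_quality_index(shuffled, 0, 4)
  expect_gt(qi_locked, qi_shuf)
  expect_equal(step_quality_index(list(numeric(0), numeric(0)), 0, 4), 0)
})

test_that("kernel quality scores extremes of the z-kernels", {
  expect_equal(kernel_quality(matrix(0, 4, 51))$score, 0)
  set.seed(8)
  noise_scores <- replicate(50, kernel_quality(matrix(rnorm(4 * 51), 4))$score)
  expect_gt(mean(noise_scores < 1000), 0.99)
  strong <- matrix(rnorm(4 * 251), 4)
  strong[1, 1:60] <- 20
  expect_gt(kernel_quality(strong)$score, 1000)
  small <- kernel_quality(rnorm(50))
  expect_true(small$truncated)
})

test_that("compound QI normalises each index to unit population mean", {
  qi_cs <- c(1, 2, 3); qi_ws <- c(2, 2, 2); qi_k <- c(10, 20, 30)
  cq <- compound_qi(qi_cs, qi_ws, qi_k)
  expect_equal(mean(cq), 1)
  # a cell sitting at twice the population mean on all three indices scores 2
  cq2 <- compound_qi(c(0, 2), c(0, 4), c(0, 6))
  expect_equal(cq2[2], 2)
  expect_equal(compound_qi(c(4, 4), c(1, 1), c(9, 9)), c(1, 1))
})

test_that("bias audit recovers monotone and null relations", {
  x <- seq(0, 1, length.out = 300)
  # binning the index ties ranks within bins, so |rho| sits just below 1
  expect_gt(bias_audit(x, x)$rho, 0.99)
  expect_lt(bias_audit(x, -x)$rho, -0.99)
  set.seed(9)
  null <- bias_audit(rnorm(3000), rnorm(3000))
  expect_lt(abs(null$rho), 0.1)
  expect_warning(res <- bias_audit(rep(1, 10), rnorm(10)), "constant")
  expect_true(is.na(res$rho))
})
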