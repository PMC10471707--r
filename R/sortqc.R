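#' @title Spike-sorting and response quality metrics
#' @name sortqc
#' @description
#' Metrics used to filter sorted cells and audit for systematic sorting
#' bias: a firing-rate exclusion rule, spatial circularity of spike
#' locations, waveform-unimodality via Hartigan's dip test, a chi-square
#' check that On/Off responses are independent of waveform sub-clusters,
#' signal-to-noise and spike-train-synchrony quality indices, kernel quality
#' scores, a population-normalised compound index, and Spearman bias audits.
NULL

#' Firing-rate exclusion rule
#'
#' Cells spiking more than 10 spikes per second on average over the session
#' are excluded (boundary kept: exactly 10 Hz passes).
#'
#' @param spike_times Numeric spike times, seconds.
#' @param duration_s Session duration, seconds (default 3600).
#' @param max_rate_hz Exclusion threshold, Hz (default 10).
#' @return TRUE to keep the cell.
#' @export
rate_exclusion <- function(spike_times, duration_s = 3600, max_rate_hz = 10) {
  stopifnot(duration_s > 0)
  length(spike_times) / duration_s <= max_rate_hz
}

#' Circularity index of a spike-location cloud
#'
#' Variance explained by the first principal component of the (x, y) spike
#' locations divided by that of the second. 1 indicates a circular cloud;
#' larger values indicate spatial skew, as for units at the array edge.
#'
#' @param locations n x 2 matrix of spike (x, y) positions.
#' @return Ratio >= 1; `Inf` for a rank-deficient (collinear) cloud.
#' @export
circularity_index <- function(locations) {
  locations <- as.matrix(locations)
  stopifnot(ncol(locations) == 2, nrow(locations) >= 3)
  ev <- stats::prcomp(locations)$sdev^2
  if (ev[2] <= .Machine$double.eps * ev[1]) return(Inf)
  ev[1] / ev[2]
}

#' Waveform-similarity test
#'
#' Projects all spike waveforms of a unit onto their first principal
#' component and tests the loading distribution for unimodality with
#' Hartigan's dip test. p near 1 suggests the waveforms come from a single
#' cell; a multimodal loading distribution (low p) flags a possible merge of
#' several cells.
#'
#' @param waveforms n x T matrix, one waveform per row (n >= 10).
#' @param n_boot Bootstrap count for the dip p-value (default 1000).
#' @param seed Seed for the bootstrap.
#' @return List with `p_value`, `dip`, and the PC1 `loadings`.
#' @export
waveform_similarity <- function(waveforms, n_boot = 1000, seed = 1) {
  waveforms <- as.matrix(waveforms)
  stopifnot(nrow(waveforms) >= 10)
  if (all(apply(waveforms, 2, stats::var) == 0)) {
    return(list(p_value = 1, dip = 0, loadings = rep(0, nrow(waveforms))))
  }
  pc <- stats::prcomp(waveforms, center = TRUE, scale. = FALSE)
  loadings <- pc$x[, 1]
  dt <- dip_test(loadings, n_boot = n_boot, seed = seed)
  list(p_value = dt$p_value, dip = dt$dip, loadings = loadings)
}

#' On/Off versus waveform-subcluster independence test
#'
#' Splits a unit's spikes into two "sub-neurons" by a 2-component Gaussian
#' mixture on the waveform PC1 loadings, then tests a 2 x 2 contingency of
#' On/Off response labels against sub-neuron membership with a chi-square
#' test. A small p suggests the unit merged an On and an Off cell.
#'
#' @param onoff_labels Character or factor vector ("On"/"Off") per spike.
#' @param pc1_loadings Numeric PC1 loading per spike.
#' @param seed Seed for the mixture fit.
#' @return List with `p_value`, `table` (2 x 2 contingency), `subcluster`.
#' @export
onoff_independence <- function(onoff_labels, pc1_loadings, seed = 1) {
  stopifnot(length(onoff_labels) == length(pc1_loadings))
  onoff_labels <- as.factor(onoff_labels)
  if (nlevels(droplevels(onoff_labels)) < 2) {
    stop("both On and Off labels must be present", call. = FALSE)
  }
  old <- withr_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  # 2-component 1-d Gaussian mixture (unequal variances) by EM, initialised
  # at the median split
  z <- mclust::unmap(as.integer(pc1_loadings > stats::median(pc1_loadings)) + 1L,
                     groups = 1:2)
  me_v <- get("meV", envir = asNamespace("mclust"))
  fit <- suppressWarnings(me_v(data = as.numeric(pc1_loadings), z = z,
                               control = mclust::emControl()))
  sub <- apply(fit$z, 1, which.max)
  tab <- table(onoff_labels, factor(sub, levels = 1:2))
  test <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
  list(p_value = test$p.value, table = tab, subcluster = sub)
}

#' Signal-to-noise ratio quality index
#'
#' `QI = Var_t[ <C>_r ] / < Var_t[C] >_r`: the variance over time of the
#' repeat-averaged response divided by the repeat-averaged variance over
#' time. 1 for perfectly repeatable responses, about 1/R for independent
#' noise across R repeats. Responses with QI below 0.4 are judged poor.
#'
#' @param C Numeric matrix, time samples x repeats (>= 2 repeats).
#' @return The quality index; NaN when all repeats are constant.
#' @export
snr_quality_index <- function(C) {
  C <- as.matrix(C)
  stopifnot(ncol(C) >= 2)
  num <- stats::var(rowMeans(C))
  den <- mean(apply(C, 2, stats::var))
  if (den == 0) return(NaN)
  num / den
}

#' Step-response quality index
#'
#' `QI = max(SYNC) - mean(ISI) + (max(PSTH) - mean(PSTH)) * std(SYNC)`,
#' where SYNC and ISI are the multivariate SPIKE-synchronization and
#' ISI-distance profiles across stimulus repeats and PSTH is the
#' peristimulus histogram over all repeats.
#'
#' @param trains List of spike-time vectors, one per repeat, on a common
#'   within-repeat time base.
#' @param t_start,t_end Repeat interval, seconds.
#' @param psth_bin_s PSTH bin width, seconds (default 0.05).
#' @return The scalar quality index; 0 when no repeat contains spikes.
#' @export
step_quality_index <- function(trains, t_start, t_end, psth_bin_s = 0.05) {
  stopifnot(length(trains) >= 2)
  all_spikes <- unlist(trains)
  all_spikes <- all_spikes[all_spikes >= t_start & all_spikes <= t_end]
  if (!length(all_spikes)) return(0)
  sync <- spike_sync_profile(trains, t_start, t_end)
  isi <- isi_profile(trains, t_start, t_end)
  breaks <- seq(t_start, t_end + psth_bin_s, by = psth_bin_s)
  psth <- graphics::hist(all_spikes, breaks = breaks, plot = FALSE)$counts /
    length(trains)
  sync_vals <- if (nrow(sync)) sync$value else 0
  max(sync_vals) - mean(isi$value) +
    (max(psth) - mean(psth)) * stats::sd(sync_vals)
}

#' Kernel quality score
#'
#' Sum of the 100 highest values plus the absolute sum of the 100 lowest
#' values of the z-normalised spectral kernels, pooled across the four
#' chromatic channels. Kernel-groups scoring below 1000 are treated as
#' non-responsive in the opponency analysis.
#'
#' @param zkernels Matrix of z-normalised kernels (LEDs x time) or vector.
#' @param n_top Number of extreme samples summed at each end (default 100).
#' @return List with `score` and `truncated` (TRUE when fewer than `n_top`
#'   samples were available).
#' @export
kernel_quality <- function(zkernels, n_top = 100) {
  v <- sort(as.numeric(zkernels))
  k <- min(n_top, length(v))
  list(score = sum(utils::tail(v, k)) + abs(sum(utils::head(v, k))),
       truncated = k < n_top)
}

#' Kernel clustering-quality (pre-selection)
#'
#' The maximum over the four LEDs of the standard deviation over time of the
#' z-normalised kernel; cells below 2.5 are judged to have poor kernels for
#' the cluster pre-selection.
#'
#' @param zkernels LEDs x time matrix of z-normalised kernels.
#' @return Maximum per-LED standard deviation.
#' @export
kernel_clustering_quality <- function(zkernels) {
  max(apply(as.matrix(zkernels), 1, stats::sd))
}

#' Compound quality index
#'
#' Each of the three per-cell quality indices (colour steps, white steps,
#' kernels) is divided by its population mean, and the three normalised
#' indices are averaged with equal weight; the population mean of the
#' compound index is therefore 1.
#'
#' @param qi_cs,qi_ws,qi_kernel Numeric vectors over the cell population.
#' @return Numeric vector of compound indices.
#' @export
compound_qi <- function(qi_cs, qi_ws, qi_kernel) {
  norm1 <- function(v) {
    m <- mean(v, na.rm = TRUE)
    if (!is.finite(m) || m == 0) {
      warning("population mean is zero; compound QI flagged", call. = FALSE)
      return(rep(NA_real_, length(v)))
    }
    v / m
  }
  (norm1(qi_cs) + norm1(qi_ws) + norm1(qi_kernel)) / 3
}

#' Spearman bias audit
#'
#' Bins cells by a response index, then rank-correlates the binned index
#' with a sorting-quality metric to detect systematic bias.
#'
#' @param index Numeric response index per cell.
#' @param metric Numeric quality metric per cell.
#' @param n_bins Number of index bins (default 10).
#' @return List with `rho`, `p_value`; rho is NA for a constant vector.
#' @export
bias_audit <- function(index, metric, n_bins = 10) {
  stopifnot(length(index) == length(metric))
  if (stats::sd(index) == 0 || stats::sd(metric) == 0) {
    warning("constant input; correlation undefined", call. = FALSE)
    return(list(rho = NA_real_, p_value = NA_real_))
  }
  bins <- as.integer(cut(index, breaks = n_bins, include.lowest = TRUE))
  ct <- suppressWarnings(
    stats::cor.test(bins, metric, method = "spearman", exact = FALSE)
  )
  list(rho = unname(ct$estimate), p_value = ct$p.value)
}
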