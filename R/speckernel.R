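#' @title Spectral kernels: per-LED linear filters from chromatic noise
#' @name speckernel
#' @description
#' Estimates each cell's four per-LED linear temporal kernels by
#' spike-triggered averaging of the binary chromatic noise stimulus: the
#' mean pre-spike stimulus segment minus the mean over all possible
#' segments, sampled finer than the 20 Hz stimulus. Kernels are
#' z-normalised against a pre-spike baseline window, and quantified by
#' amplitude, spectral centroid (kinetics) and time-resolved colour
#' opponency.
NULL

#' Estimate spectral kernels by spike-triggered averaging
#'
#' For each LED, the mean stimulus segment over the `window_s` seconds
#' preceding each spike (sampled every `step_s`; a spike may fall anywhere
#' within a stimulus frame, so the segments resolve finer than the stimulus
#' itself), minus the mean over all possible segments. The z-normalised
#' variant subtracts the mean and divides by the SD of a kernel computed
#' identically over the `baseline_window` interval preceding each spike.
#'
#' @param spike_times Spike times, seconds, within the noise run.
#' @param noise A `noise_sequence` from [build_spectral_noise()].
#' @param window_s Kernel window before the spike, seconds (default 1).
#' @param step_s Kernel sampling interval, seconds (default 0.02 giving 51
#'   points; use 0.001 for the 1 ms opponency grid).
#' @param baseline_window Baseline interval before each spike, seconds
#'   (default `c(2, 1)`, i.e. [-2, -1] s).
#' @return A `spectral_kernel_set`: list with `time` (negative, ending at
#'   0), `raw` and `z` (4 x n_points matrices, rows R, G, C, B),
#'   `n_spikes`, `baseline_mean`, `baseline_sd`.
#' @export
compute_kernel <- function(spike_times, noise, window_s = 1, step_s = 0.02,
                           baseline_window = c(2, 1)) {
  stopifnot(inherits(noise, "noise_sequence"))
  dur <- noise$n_frames / noise$frame_rate
  lead <- max(window_s, baseline_window[1])
  valid <- spike_times[spike_times >= lead & spike_times <= dur]
  offs <- seq(-window_s, 0, by = step_s)
  n_pts <- length(offs)
  led_names <- colnames(noise$values)
  if (!length(valid)) {
    warning("no spikes with a full pre-spike window", call. = FALSE)
    empty <- matrix(NA_real_, 4, n_pts, dimnames = list(led_names, NULL))
    return(structure(list(time = offs, raw = empty, z = empty, n_spikes = 0L,
                          baseline_mean = rep(NA_real_, 4),
                          baseline_sd = rep(NA_real_, 4)),
                     class = "spectral_kernel_set"))
  }
  seg_mean <- function(offsets) {
    # mean over spikes of the stimulus at (spike + offset), per LED
    out <- matrix(0, 4, length(offsets), dimnames = list(led_names, NULL))
    for (k in seq_along(offsets)) {
      out[, k] <- colMeans(sample_frames(noise$values, noise$frame_rate,
                                         valid + offsets[k]))
    }
    out
  }
  # mean raw stimulus: mean over all possible segment initiation times on
  # the step_s grid; by stationarity each offset has the same grand mean
  starts <- seq(lead, dur, by = step_s)
  grand <- colMeans(sample_frames(noise$values, noise$frame_rate, starts))
  raw <- sweep(seg_mean(offs), 1, grand)
  base_offs <- seq(-baseline_window[1], -baseline_window[2], by = step_s)
  base <- sweep(seg_mean(base_offs), 1, grand)
  bm <- rowMeans(base)
  bs <- apply(base, 1, stats::sd)
  bs[bs == 0] <- NA_real_
  z <- sweep(sweep(raw, 1, bm), 1, bs, `/`)
  structure(list(time = offs, raw = raw, z = z, n_spikes = length(valid),
                 baseline_mean = bm, baseline_sd = bs),
            class = "spectral_kernel_set")
}

#' @export
print.spectral_kernel_set <- function(x, ...) {
  cat(sprintf("<spectral_kernel_set> %d points over [%g, 0] s, %d spikes\n",
              length(x$time), min(x$time), x$n_spikes))
  invisible(x)
}

#' Kernel amplitudes
#'
#' Per-LED amplitude of the z-normalised kernels as the difference between
#' their maximum and minimum; kernel sets whose largest amplitude is below
#' `threshold` are flagged discarded.
#'
#' @param kernels A `spectral_kernel_set` or a 4 x n z-kernel matrix.
#' @param threshold Discard threshold in z units (default 2.5).
#' @return List with `per_led` (named amplitudes), `max_amplitude`,
#'   `discarded`.
#' @export
kernel_amplitude <- function(kernels, threshold = 2.5) {
  zk <- if (inherits(kernels, "spectral_kernel_set")) kernels$z else as.matrix(kernels)
  amps <- apply(zk, 1, function(v) {
    if (all(is.na(v))) return(NA_real_)
    max(v, na.rm = TRUE) - min(v, na.rm = TRUE)
  })
  mx <- if (all(is.na(amps))) NA_real_ else max(amps, na.rm = TRUE)
  list(per_led = amps, max_amplitude = mx,
       discarded = is.na(mx) || mx < threshold)
}

#' Spectral centroid of a kernel
#'
#' The kernel's kinetics summarised as a central frequency: the kernel is
#' mean-subtracted, zero-padded, and its area-normalised magnitude-squared
#' Fourier transform taken as a probability mass function over positive
#' frequencies. The default convention returns the frequency-weighted mean
#' `sum(PMF * f)` in Hz; `convention = "reciprocal"` instead weights each
#' entry by the reciprocal of its frequency and returns the sum of that
#' product.
#'
#' @param kernel Numeric kernel time series.
#' @param sampling_rate_hz Kernel sampling rate, Hz (default 50, the 20 ms
#'   grid).
#' @param pad_to FFT length after zero-padding (default 256).
#' @param convention `"frequency"` (default) or `"reciprocal"`.
#' @return Centroid (Hz for the default convention); NA for a flat kernel.
#' @export
spectral_centroid <- function(kernel, sampling_rate_hz = 50, pad_to = 256,
                              convention = c("frequency", "reciprocal")) {
  convention <- match.arg(convention)
  kernel <- kernel[!is.na(kernel)]
  if (length(kernel) < 2 || stats::sd(kernel) == 0) return(NA_real_)
  x <- kernel - mean(kernel)
  n <- max(pad_to, length(x))
  x <- c(x, numeric(n - length(x)))
  sp <- Mod(stats::fft(x))^2
  half <- 2:(floor(n / 2) + 1)          # positive frequencies, exclude DC
  freq <- (half - 1) * sampling_rate_hz / n
  pmf <- sp[half] / sum(sp[half])
  if (convention == "frequency") sum(pmf * freq) else sum(pmf / freq)
}

#' Classify per-bin colour opponency
#'
#' On a common (typically 1 ms) time grid, each bin is non-responsive when
#' no kernel reaches `amp_threshold` in absolute value; otherwise it is
#' opponent (1) when the supra-threshold kernels disagree in sign and
#' non-opponent (0) when they all share one sign.
#'
#' @param zkernels 4 x n matrix of z-normalised kernels on the fine grid.
#' @param amp_threshold Minimum absolute amplitude (default 3; use 1.5 for
#'   cluster means).
#' @return An `opponency_profile`: list with `labels` (per bin: NA
#'   non-responsive, 0 non-opponent, 1 opponent) and `amp_threshold`.
#' @export
classify_opponency <- function(zkernels, amp_threshold = 3) {
  zk <- if (inherits(zkernels, "spectral_kernel_set")) zkernels$z else as.matrix(zkernels)
  n <- ncol(zk)
  labels <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    v <- zk[, i]
    supra <- v[!is.na(v) & abs(v) >= amp_threshold]
    if (!length(supra)) next
    labels[i] <- as.numeric(any(supra > 0) && any(supra < 0))
  }
  structure(list(labels = labels, amp_threshold = amp_threshold),
            class = "opponency_profile")
}

#' Colour opponency index
#'
#' The mean of the 0/1 opponency labels over responsive bins, defined only
#' when at least `min_opponent_bins` bins are opponent and the kernel
#' quality score reaches `min_kernel_qi`; otherwise the kernel group is
#' treated as non-opponent (NA).
#'
#' @param profile An `opponency_profile`.
#' @param kernel_qi Kernel quality score of the set (see
#'   [kernel_quality()]); default `Inf` skips the check.
#' @param min_opponent_bins Minimum opponent bins (default 20).
#' @param min_kernel_qi Quality exclusion bound (default 1000).
#' @return COI in [0, 1], or NA when undefined.
#' @export
colour_opponency_index <- function(profile, kernel_qi = Inf,
                                   min_opponent_bins = 20,
                                   min_kernel_qi = 1000) {
  lab <- profile$labels
  resp <- lab[!is.na(lab)]
  if (!length(resp)) return(NA_real_)
  if (kernel_qi < min_kernel_qi) return(NA_real_)
  if (sum(resp == 1) < min_opponent_bins) return(NA_real_)
  mean(resp)
}

#' Time-normalised opponency vector
#'
#' Rescales the opponency profile's time axis so that the response onset
#' (first bin where any kernel exceeds `onset_threshold` in absolute value)
#' maps to -1 and the spike to 0, resampling onto a regular grid. Opponent
#' bins keep +1; non-opponent bins are recoded -1; non-responsive bins stay
#' NA.
#'
#' @param profile An `opponency_profile`.
#' @param zkernels The z-kernel matrix the profile was computed from.
#' @param onset_threshold Onset amplitude in z units (default 1).
#' @param n_out Output grid length (default 1000).
#' @return List with `time` (from -1 to 0) and `values` in {-1, +1, NA}, or
#'   NULL (flagged) when no bin exceeds the onset threshold.
#' @export
time_normalised_opponency <- function(profile, zkernels, onset_threshold = 1,
                                      n_out = 1000) {
  zk <- if (inherits(zkernels, "spectral_kernel_set")) zkernels$z else as.matrix(zkernels)
  peak <- apply(abs(zk), 2, max, na.rm = TRUE)
  onset <- which(peak >= onset_threshold)[1]
  if (is.na(onset)) {
    warning("no bin exceeds the onset threshold", call. = FALSE)
    return(NULL)
  }
  lab <- profile$labels
  n <- length(lab)
  if (onset >= n) onset <- n - 1L
  seg <- lab[onset:n]
  recoded <- ifelse(is.na(seg), NA_real_, ifelse(seg == 1, 1, -1))
  src_t <- seq(-1, 0, length.out = length(seg))
  out_t <- seq(-1, 0, length.out = n_out)
  idx <- pmin(length(seg), pmax(1L, round((out_t + 1) * (length(seg) - 1)) + 1L))
  list(time = out_t, values = recoded[idx])
}
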