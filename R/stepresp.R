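#' @title Step-response rates, amplitudes and response indices
#' @name stepresp
#' @description
#' Turns step-stimulus spike trains into kernel-density rate traces and the
#' response indices used throughout: polarity (PI), transience (TI),
#' spectral dominance (SD), spectral tuning against log-transformed visual
#' pigment nomograms (ST), and response latency; includes the step-response
#' PCA over colour/contrast series and harmonisation of external datasets.
NULL

#' Kernel-density spiking-rate trace
#'
#' Spike times are mapped onto the first-repeat interval and smoothed by a
#' Gaussian kernel density estimate at 1000 evenly spaced points (bandwidth
#' 0.05 s), so that the area under the curve is one: rates are normalised
#' across cells and stimuli.
#'
#' @param spike_times Spike times, seconds (absolute over repeats).
#' @param duration_s Single-repeat duration, seconds.
#' @param bandwidth Gaussian kernel sd, seconds (default 0.05).
#' @param n_points Number of evaluation points (default 1000).
#' @return List with `time`, `rate` (density), `bandwidth`, `n_spikes`,
#'   `integral` (area over the support).
#' @export
kde_rate <- function(spike_times, duration_s, bandwidth = 0.05,
                     n_points = 1000) {
  t_grid <- seq(0, duration_s, length.out = n_points)
  if (!length(spike_times)) {
    return(list(time = t_grid, rate = numeric(n_points), bandwidth = bandwidth,
                n_spikes = 0L, integral = 0))
  }
  mapped <- map_to_first_repeat(spike_times, duration_s)
  d <- stats::density(mapped, bw = bandwidth, from = 0, to = duration_s,
                      n = n_points)
  integral <- sum(d$y) * (t_grid[2] - t_grid[1])
  list(time = d$x, rate = d$y, bandwidth = bandwidth,
       n_spikes = length(mapped), integral = integral)
}

# Smoothed firing-rate trace (spikes/s per repeat) from mapped spike times.
rate_trace <- function(mapped_times, n_repeats, duration_s, bin_s = 0.01,
                       smooth_s = 0.04) {
  breaks <- seq(0, duration_s + bin_s, by = bin_s)
  counts <- graphics::hist(mapped_times, breaks = breaks, plot = FALSE)$counts
  rate <- counts / n_repeats / bin_s
  list(time = utils::head(breaks, -1) + bin_s / 2,
       rate = box_smooth(rate, round(smooth_s / bin_s)))
}

#' Step-response amplitude measures
#'
#' For each On/Off epoch of a step timeline: the mean number of spikes over
#' the full epoch (`a_mean`), and the peak of the 40 ms box-smoothed rate in
#' the transient (80-160 ms) and sustained (240-2000 ms) windows after the
#' transition (`a_tr`, `a_sus`).
#'
#' @param spike_times Spike times, absolute over repeats, seconds.
#' @param timeline The step `stimulus_timeline` the spikes answer.
#' @param n_repeats Number of stimulus repeats.
#' @param tr_window,sus_window Transient and sustained windows after the
#'   transition, seconds.
#' @param smooth_s Box-smoothing window, seconds (default 0.04).
#' @return data.frame, one row per epoch: `kind`, `parameter`, `a_mean`,
#'   `a_tr`, `a_sus`.
#' @export
response_amplitudes <- function(spike_times, timeline, n_repeats,
                                tr_window = c(0.08, 0.16),
                                sus_window = c(0.24, 2.0), smooth_s = 0.04) {
  dur <- timeline$duration_s
  mapped <- map_to_first_repeat(spike_times, dur)
  tr <- rate_trace(mapped, n_repeats, dur, smooth_s = smooth_s)
  ep <- timeline$epochs
  out <- ep[, c("kind", "parameter")]
  out$a_mean <- out$a_tr <- out$a_sus <- NA_real_
  for (i in seq_len(nrow(ep))) {
    t0 <- ep$start_s[i]
    t1 <- ep$end_s[i]
    out$a_mean[i] <- sum(mapped >= t0 & mapped < t1) / n_repeats
    win <- function(w) {
      sel <- tr$time >= t0 + w[1] & tr$time <= min(t0 + w[2], t1)
      if (!any(sel)) 0 else max(tr$rate[sel])
    }
    out$a_tr[i] <- win(tr_window)
    out$a_sus[i] <- win(sus_window)
  }
  out
}

#' Baseline rate as the amplitude-histogram mode
#'
#' A 1000-bin amplitude histogram of the concatenated white-step and
#' colour-step cluster-mean trace; the centre of the most populated bin is
#' the baseline (ties broken towards the lowest bin).
#'
#' @param trace Numeric rate trace (concatenated WS + CS responses).
#' @param n_bins Histogram bins (default 1000).
#' @return Baseline rate (bin centre).
#' @export
estimate_baseline <- function(trace, n_bins = 1000) {
  stopifnot(length(trace) > 0)
  rng <- range(trace)
  if (rng[1] == rng[2]) return(rng[1])
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  counts <- graphics::hist(trace, breaks = breaks, plot = FALSE)$counts
  i <- which.max(counts)  # which.max returns the first (lowest) max bin
  (breaks[i] + breaks[i + 1]) / 2
}

# Shared contrast form of the paired indices; NaN (flagged) when both zero.
.contrast_index <- function(a, b) {
  if (a + b == 0) {
    warning("undefined index: both amplitudes zero", call. = FALSE)
    return(NaN)
  }
  (a - b) / (a + b)
}

#' Polarity index
#'
#' `PI = (A_On - A_Off) / (A_On + A_Off)` on the 100% contrast white-step
#' amplitudes: -1 purely Off, +1 purely On.
#'
#' @param a_on,a_off On and Off response amplitudes (>= 0).
#' @return PI in [-1, 1]; NaN when both are zero.
#' @export
polarity_index <- function(a_on, a_off) .contrast_index(a_on, a_off)

#' Transience index
#'
#' `TI = (A_Tr - A_Sus) / (A_Tr + A_Sus)`: +1 purely transient, negative for
#' temporally increasing (sustained-dominated) responses.
#'
#' @param a_tr,a_sus Transient and sustained peak amplitudes.
#' @return TI in [-1, 1]; NaN when both are zero.
#' @export
transience_index <- function(a_tr, a_sus) .contrast_index(a_tr, a_sus)

#' Compound transience index
#'
#' Uses the On-variant when the polarity index is non-negative, otherwise
#' the Off-variant: the dominant polarity dictates which transience applies.
#'
#' @param ti_on,ti_off On- and Off-transience indices.
#' @param pi Polarity index.
#' @return The selected transience index.
#' @export
compound_ti <- function(ti_on, ti_off, pi) {
  if (is.nan(pi)) return(NaN)
  if (pi >= 0) ti_on else ti_off
}

#' Spectral dominance index
#'
#' `SD = (A_colour - A_white) / (A_colour + A_white)` on the transient
#' amplitudes of the largest colour-step response and the 100% white step.
#'
#' @param a_colour,a_white Transient amplitudes.
#' @return SD in [-1, 1]; NaN when both are zero.
#' @export
spectral_dominance <- function(a_colour, a_white) {
  .contrast_index(a_colour, a_white)
}

#' Visual pigment absorbance nomogram (A1 template)
#'
#' The standard A1 pigment alpha-band template with its beta band, peak
#' normalised to 1 at `lambda_max`.
#'
#' @param lambda Wavelength(s), nm.
#' @param lambda_max Peak-sensitivity wavelength, nm.
#' @return Linear sensitivity in (0, 1].
#' @export
pigment_nomogram <- function(lambda, lambda_max) {
  x <- lambda_max / lambda
  a <- 0.8795 + 0.0459 * exp(-(lambda_max - 300)^2 / 11940)
  s_alpha <- 1 / (exp(69.7 * (a - x)) + exp(28 * (0.922 - x)) +
                    exp(-14.9 * (1.104 - x)) + 0.674)
  lmb <- 189 + 0.315 * lambda_max
  bb <- -40.5 + 0.195 * lambda_max
  s <- s_alpha + 0.26 * exp(-((lambda - lmb) / bb)^2)
  # renormalise: the beta band lifts the curve slightly off 1 at the peak
  grid <- seq(300, 750, by = 0.5)
  xg <- lambda_max / grid
  sg <- 1 / (exp(69.7 * (a - xg)) + exp(28 * (0.922 - xg)) +
               exp(-14.9 * (1.104 - xg)) + 0.674) +
    0.26 * exp(-((grid - lmb) / bb)^2)
  s / max(sg)
}

#' Log-transformed opsin template
#'
#' The nomogram stretched over one log-unit: a linear sensitivity of 100%
#' maps to 1 and 10% to 0 (`T = max(0, 1 + log10(S))`), reflecting the
#' roughly 10-fold operating range of cone phototransduction. Values below
#' 10% of maximum clip to 0.
#'
#' @param lambda_max Peak wavelength, nm.
#' @param wavelengths Wavelengths at which to evaluate, nm.
#' @return Numeric vector in [0, 1].
#' @export
opsin_template <- function(lambda_max, wavelengths) {
  s <- pigment_nomogram(wavelengths, lambda_max)
  pmax(0, 1 + log10(s))
}

#' Default chick cone-opsin peak wavelengths
#'
#' Configurable defaults for the four single-cone opsin classes.
#'
#' @return Named numeric vector (nm) for LWS, RH2, SWS2, SWS1.
#' @export
chick_opsin_lmax <- function() {
  c(LWS = 571, RH2 = 508, SWS2 = 455, SWS1 = 419)
}

#' Spectral tuning index
#'
#' Finds the opsin template best matching a normalised 6-point spectral
#' tuning function (Pearson correlation at the LED wavelengths), then
#' `ST = -mean(tuning - template)`: 0 for a perfect match, positive for
#' tuning narrower than the opsin, negative for broader.
#'
#' @param tuning Length-6 tuning function normalised 0 (baseline) to 1
#'   (peak), ordered as `led_specs()` (R to U).
#' @param peak_spikes Peak response in spikes; below `min_spikes` the index
#'   is not computed (NA).
#' @param lmax_set Named opsin peak wavelengths (default chick set).
#' @param wavelengths LED wavelengths, nm.
#' @param min_spikes Minimum peak response (default 3).
#' @return List with `st`, `best_class`, `template` (6 values).
#' @export
spectral_tuning_index <- function(tuning, peak_spikes = Inf,
                                  lmax_set = chick_opsin_lmax(),
                                  wavelengths = led_specs()$wavelength_nm,
                                  min_spikes = 3) {
  stopifnot(length(tuning) == length(wavelengths))
  if (peak_spikes < min_spikes) {
    return(list(st = NA_real_, best_class = NA_character_, template = NULL))
  }
  templates <- vapply(lmax_set, opsin_template, numeric(length(wavelengths)),
                      wavelengths = wavelengths)
  cors <- apply(templates, 2, function(tp) {
    if (stats::sd(tp) == 0 || stats::sd(tuning) == 0) -Inf
    else stats::cor(tuning, tp)
  })
  best <- which.max(cors)
  tmpl <- templates[, best]
  list(st = -mean(tuning - tmpl), best_class = names(lmax_set)[best],
       template = tmpl)
}

#' Response latency (time to half peak)
#'
#' On the 40 ms box-smoothed rate trace, the time from the step transition
#' to the first crossing of half the post-transition peak.
#'
#' @param time,rate Rate trace (regular sampling assumed).
#' @param transition_s Transition time, seconds.
#' @param window_s Search window after the transition (default 2 s).
#' @param smooth_s Box-smoothing window (default 0.04; set 0 if the trace is
#'   already smoothed).
#' @return Latency in seconds; NA (flagged) when there is no response.
#' @export
response_latency <- function(time, rate, transition_s, window_s = 2,
                             smooth_s = 0.04) {
  dt <- time[2] - time[1]
  if (smooth_s > 0) rate <- box_smooth(rate, max(1, round(smooth_s / dt)))
  sel <- which(time >= transition_s & time <= transition_s + window_s)
  if (!length(sel)) return(NA_real_)
  seg <- rate[sel]
  pk <- max(seg)
  if (pk <= 0) {
    warning("no positive response after transition", call. = FALSE)
    return(NA_real_)
  }
  cross <- which(seg >= pk / 2)[1]
  time[sel[cross]] - transition_s
}

#' Step-response principal component analysis
#'
#' Combines ten step responses (by convention the first five colour steps,
#' excluding UV, and the 100-60% contrast white steps), each resampled to 50
#' bins of 20 ms with the first 4 bins (80 ms) zeroed to exclude residual
#' activity, and extracts the first two principal components. Components are
#' oriented so their largest-magnitude value is positive; loadings are
#' peak-normalised to 1.
#'
#' @param responses 50 x m matrix (time bins x responses, typically m = 10).
#' @param zero_bins Number of leading bins to zero (default 4).
#' @return List with `components` (50 x 2), `loadings` (m x 2,
#'   peak-normalised), `var_explained` (length 2 fractions).
#' @export
step_pca <- function(responses, zero_bins = 4) {
  responses <- as.matrix(responses)
  responses[seq_len(zero_bins), ] <- 0
  pc <- stats::prcomp(t(responses), center = TRUE, scale. = FALSE)
  if (length(pc$sdev) < 2 || pc$sdev[2]^2 < 1e-12 * pc$sdev[1]^2) {
    warning("response matrix has rank < 2", call. = FALSE)
  }
  comps <- pc$rotation[, 1:2, drop = FALSE]
  loads <- pc$x[, 1:2, drop = FALSE]
  for (j in seq_len(ncol(comps))) {
    if (comps[which.max(abs(comps[, j])), j] < 0) {
      comps[, j] <- -comps[, j]
      loads[, j] <- -loads[, j]
    }
    pkload <- max(abs(loads[, j]))
    if (pkload > 0) loads[, j] <- loads[, j] / pkload
  }
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  list(components = comps, loadings = loads, var_explained = ve[1:2])
}

#' Harmonise an external step-response trace
#'
#' Pre-processing for cross-species comparison: optional exponential-kernel
#' deconvolution (for calcium traces; `y[t] - exp(-dt/tau) y[t-1]` inverts
#' convolution with a `tau`-decaying kernel), cropping of the first second
#' after each On/Off transition, resampling into 50 bins of 20 ms, then the
#' polarity and transience indices on the cropped windows. A polarity's
#' histogram inclusion flag requires the weaker polarity to exceed
#' `min_resp_frac` of the stronger.
#'
#' @param time,value The response trace (regularly sampled).
#' @param on_transitions,off_transitions Transition times, seconds.
#' @param window_s Cropped window, seconds (default 1).
#' @param n_bins Resampled bins (default 50).
#' @param deconv_tau_s Deconvolution time constant, seconds, or NULL.
#' @param min_resp_frac Weaker-polarity inclusion threshold (default 0.2).
#' @return List with `pi`, `ti_on`, `ti_off`, `on_trace`, `off_trace`
#'   (50-bin means), `include_on`, `include_off`.
#' @export
harmonise_external <- function(time, value, on_transitions, off_transitions,
                               window_s = 1, n_bins = 50,
                               deconv_tau_s = NULL, min_resp_frac = 0.2) {
  dt <- time[2] - time[1]
  if (!is.null(deconv_tau_s)) {
    a <- exp(-dt / deconv_tau_s)
    value <- c(value[1], value[-1] - a * value[-length(value)])
  }
  base <- estimate_baseline(value)
  crop <- function(transitions) {
    segs <- lapply(transitions, function(t0) {
      grid <- seq(t0, t0 + window_s - window_s / n_bins,
                  length.out = n_bins) + window_s / n_bins / 2
      stats::approx(time, value, xout = grid, rule = 2)$y
    })
    rowMeans(do.call(cbind, segs)) - base
  }
  on_trace <- crop(on_transitions)
  off_trace <- crop(off_transitions)
  amp <- function(tr) max(0, sum(pmax(tr, 0)))
  a_on <- amp(on_trace)
  a_off <- amp(off_trace)
  pi_v <- if (a_on + a_off > 0) (a_on - a_off) / (a_on + a_off) else NaN
  bin_s <- window_s / n_bins
  ti_of <- function(tr) {
    tt <- (seq_len(n_bins) - 0.5) * bin_s
    peak_in <- function(w) {
      sel <- tt >= w[1] & tt <= w[2]
      if (!any(sel)) 0 else max(0, max(tr[sel]))
    }
    a_tr <- peak_in(c(0.08, 0.16))
    a_sus <- peak_in(c(0.24, window_s))
    if (a_tr + a_sus == 0) NaN else (a_tr - a_sus) / (a_tr + a_sus)
  }
  stronger <- max(a_on, a_off)
  list(pi = pi_v, ti_on = ti_of(on_trace), ti_off = ti_of(off_trace),
       on_trace = on_trace, off_trace = off_trace,
       include_on = a_on > min_resp_frac * stronger,
       include_off = a_off > min_resp_frac * stronger)
}
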