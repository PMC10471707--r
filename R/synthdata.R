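#' @title Ground-truth synthetic data: LNP spiking cells and electrical footprints
#' @name synthdata
#' @description
#' A linear-nonlinear-Poisson (LNP) simulator with configurable polarity mix,
#' kinetics, spectral weights and colour opponency, plus a synthetic
#' electrical-footprint generator placing a biphasic soma waveform and a
#' propagating axon signal on the 64 x 64 electrode grid. Every downstream
#' analysis stage has a parameter-recovery test against these ground truths.
NULL

#' Construct a ground-truth LNP cell
#'
#' @param id Cell identifier (character or integer).
#' @param baseline_rate Spontaneous rate, Hz (>= 0).
#' @param gain Response gain, Hz per unit of rectified drive.
#' @param on_weight,off_weight Non-negative weights of the On (positive
#'   drive) and Off (negative drive) rectified branches.
#' @param filter_kind `"monophasic"` or `"biphasic"` temporal filter.
#' @param tau_s Filter time constant, seconds.
#' @param spectral_weights Signed 6-vector of per-LED weights in the order
#'   R, Y, G, C, B, U.
#' @param opponent Optional list(`weights` = 6-vector, `tau_s`, `filter_kind`)
#'   describing a second, opposed chromatic pathway with its own kinetics,
#'   summed into the same drive.
#' @param off_pathway Optional list(`weights`, `tau_s`, `filter_kind`): a
#'   separate drive for the Off branch. When the On and Off circuits
#'   integrate different spectra and kinetics, an OnOff cell's linear
#'   kernels become time-dependently colour opponent; without it a balanced
#'   OnOff cell's rectification is even in the drive and its linear kernel
#'   cancels.
#' @param refractory_s Absolute refractory period, seconds (default 0.002).
#' @param latency_s Pure response delay modelling phototransduction and inner
#'   retinal processing, seconds (default 0.1).
#' @return A `gt_cell` list.
#' @export
gt_cell <- function(id, baseline_rate = 1, gain = 30,
                    on_weight = 1, off_weight = 0,
                    filter_kind = c("monophasic", "biphasic"),
                    tau_s = 0.08,
                    spectral_weights = rep(1, 6),
                    opponent = NULL, off_pathway = NULL,
                    refractory_s = 0.002, latency_s = 0.1) {
  filter_kind <- match.arg(filter_kind)
  stopifnot(baseline_rate >= 0, on_weight >= 0, off_weight >= 0, tau_s > 0,
            length(spectral_weights) == 6)
  structure(
    list(id = id, baseline_rate = baseline_rate, gain = gain,
         on_weight = on_weight, off_weight = off_weight,
         filter_kind = filter_kind, tau_s = tau_s,
         spectral_weights = spectral_weights, opponent = opponent,
         off_pathway = off_pathway,
         refractory_s = refractory_s, latency_s = latency_s),
    class = "gt_cell"
  )
}

#' Temporal filter of an LNP cell
#'
#' Monophasic: an alpha function `t exp(-t/tau)`; biphasic: difference of two
#' alpha functions with the rebound lobe at `2 tau`. Peak-normalised to 1.
#'
#' @param kind `"monophasic"` or `"biphasic"`.
#' @param tau_s Time constant, seconds.
#' @param dt Sample interval, seconds.
#' @param span_s Filter support, seconds; the default covers the slowest
#'   lobe (the biphasic rebound evolves on `2 * tau_s`).
#' @return Numeric vector of filter taps, causal, peak magnitude 1.
#' @export
lnp_filter <- function(kind, tau_s, dt,
                       span_s = if (kind == "biphasic") 14 * tau_s else 7 * tau_s) {
  t <- seq(0, span_s, by = dt)
  k <- if (kind == "monophasic") {
    t * exp(-t / tau_s)
  } else {
    # rebound lobe at twice the time constant, weighted for zero net
    # integral: a pure transient (change) detector
    t * exp(-t / tau_s) - 0.25 * t * exp(-t / (2 * tau_s))
  }
  k / max(abs(k))
}

# Linear drive of one cell for a stimulus sampled at dt; stimulus columns are
# centred on their temporal mean so On and Off transitions drive symmetric
# positive/negative excursions.
lnp_drive <- function(cell, stim, dt) {
  centred <- sweep(stim, 2, colMeans(stim))
  drive_for <- function(w, kind, tau) {
    active <- which(w != 0)
    if (!length(active)) return(numeric(nrow(stim)))
    k <- lnp_filter(kind, tau, dt)
    k <- k / sum(abs(k))          # unit L1 mass: drive on stimulus scale
    x <- as.numeric(centred[, active, drop = FALSE] %*% w[active])
    conv_causal(x, k)
  }
  d <- drive_for(cell$spectral_weights, cell$filter_kind, cell$tau_s)
  if (!is.null(cell$opponent)) {
    op <- cell$opponent
    d <- d + drive_for(op$weights,
                       if (is.null(op$filter_kind)) cell$filter_kind else op$filter_kind,
                       op$tau_s)
  }
  # pure latency delay
  shift <- round(cell$latency_s / dt)
  if (shift > 0) d <- c(numeric(shift), d[seq_len(length(d) - shift)])
  d
}

# Instantaneous firing rate (Hz) of a cell under a stimulus matrix. The Off
# branch rectifies its own drive when an off_pathway is configured.
lnp_rate <- function(cell, stim, dt) {
  d_on <- lnp_drive(cell, stim, dt)
  d_off <- if (is.null(cell$off_pathway)) d_on else {
    op <- cell$off_pathway
    cell_off <- cell
    cell_off$spectral_weights <- op$weights
    cell_off$tau_s <- op$tau_s
    if (!is.null(op$filter_kind)) cell_off$filter_kind <- op$filter_kind
    cell_off$opponent <- NULL
    lnp_drive(cell_off, stim, dt)
  }
  r <- cell$baseline_rate +
    cell$gain * (cell$on_weight * pmax(0, d_on) +
                   cell$off_weight * pmax(0, -d_off))
  pmax(0, r)
}

# Stimulus matrix (time x 6 LEDs) on a dt grid for a timeline or noise object.
stim_on_grid <- function(timeline, dt) {
  if (inherits(timeline, "noise_sequence")) {
    dur <- timeline$n_frames / timeline$frame_rate
    t <- seq(0, dur - dt, by = dt)
    vals <- sample_frames(timeline$values, timeline$frame_rate, t)
    # noise drives R, G, C, B; Y and U stay dark
    stim <- matrix(0, nrow = length(t), ncol = 6)
    colnames(stim) <- led_specs()$name
    stim[, c("R", "G", "C", "B")] <- vals
    list(stim = stim, duration = dur)
  } else {
    t <- seq(0, timeline$duration_s - dt, by = dt)
    list(stim = sample_frames(timeline$frames, timeline$frame_rate, t),
         duration = timeline$duration_s)
  }
}

#' Simulate spike trains from LNP cells
#'
#' Drives each cell's linear stage with the stimulus, rectifies into On and
#' Off branches weighted by the cell's polarity mix, and draws spikes from an
#' inhomogeneous Poisson process with an absolute refractory period. Repeats
#' are simulated independently and concatenated in time.
#'
#' @param cells List of [gt_cell()] objects.
#' @param timeline A `stimulus_timeline` or `noise_sequence`.
#' @param n_repeats Number of stimulus repeats (default 1).
#' @param seed Integer seed.
#' @param dt Simulation step, seconds (default 0.001).
#' @return A data.frame with columns `cell_id`, `time_s` (absolute over the
#'   concatenated repeats), `repeat_idx`, `repeat_time_s`; attribute
#'   `duration_s` holds the single-repeat duration.
#' @export
simulate_lnp <- function(cells, timeline, n_repeats = 1, seed = 1, dt = 0.001) {
  old <- withr_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  grid <- stim_on_grid(timeline, dt)
  nt <- nrow(grid$stim)
  out <- vector("list", length(cells) * n_repeats)
  ii <- 0L
  for (cell in cells) {
    rate <- lnp_rate(cell, grid$stim, dt)
    p <- pmin(1, rate * dt)
    ref_bins <- max(0L, round(cell$refractory_s / dt))
    for (rep_i in seq_len(n_repeats)) {
      hits <- which(stats::runif(nt) < p)
      if (length(hits) > 1 && ref_bins > 0) {
        keep <- logical(length(hits))
        last <- -Inf
        for (j in seq_along(hits)) {
          if (hits[j] - last > ref_bins) {
            keep[j] <- TRUE
            last <- hits[j]
          }
        }
        hits <- hits[keep]
      }
      tt <- (hits - 1) * dt + stats::runif(length(hits)) * dt
      tt <- sort(tt)
      ii <- ii + 1L
      out[[ii]] <- data.frame(
        cell_id = rep(cell$id, length(tt)),
        time_s = tt + (rep_i - 1) * grid$duration,
        repeat_idx = rep(rep_i, length(tt)),
        repeat_time_s = tt,
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out[seq_len(ii)])
  rownames(res) <- NULL
  attr(res, "duration_s") <- grid$duration
  attr(res, "n_repeats") <- n_repeats
  res
}

#' Construct a synthetic axon on the electrode grid
#'
#' @param soma (row, col) soma position on the 64 x 64 grid.
#' @param path_points Matrix of (row, col) polyline vertices starting adjacent
#'   to the soma, or NULL for a soma-only (axonless) cell.
#' @param velocity_m_s Conduction velocity, m/s (> 0).
#' @param soma_amplitude_uv Peak-to-trough soma amplitude, microvolts.
#' @param spatial_sigma Gaussian spatial decay of the soma signal, channel
#'   pitches.
#' @param axon_amplitude_uv Trough amplitude on axon channels.
#' @param electrode_pitch_mm Inter-electrode pitch, mm (default 0.042).
#' @param sampling_rate Hz (default 18000).
#' @return A `synthetic_axon` list including the rasterised channel `path`
#'   with per-channel arclength (mm) and delay (frames).
#' @export
synthetic_axon <- function(soma, path_points = NULL, velocity_m_s = 1,
                           soma_amplitude_uv = 100, spatial_sigma = 1.2,
                           axon_amplitude_uv = 35,
                           electrode_pitch_mm = 0.042, sampling_rate = 18000) {
  stopifnot(velocity_m_s > 0, length(soma) == 2)
  path <- NULL
  if (!is.null(path_points)) {
    path_points <- rbind(matrix(soma, ncol = 2), path_points)
    if (any(path_points < 1 | path_points > 64)) {
      stop("axon path leaves the 64 x 64 grid", call. = FALSE)
    }
    # rasterise polyline at ~1 channel-pitch steps, dropping the soma vertex
    pts <- list()
    for (i in seq_len(nrow(path_points) - 1)) {
      a <- path_points[i, ]
      b <- path_points[i + 1, ]
      seg_len <- sqrt(sum((b - a)^2))
      nstep <- max(1L, ceiling(seg_len))
      frac <- seq_len(nstep) / nstep
      pts[[i]] <- cbind(a[1] + frac * (b[1] - a[1]),
                        a[2] + frac * (b[2] - a[2]))
    }
    pts <- unique(round(do.call(rbind, pts)))
    pts <- pts[!(pts[, 1] == soma[1] & pts[, 2] == soma[2]), , drop = FALSE]
    if (nrow(pts) > 0) {
      d <- sqrt(rowSums(sweep(pts, 2, soma)^2))  # radial arclength proxy
      # cumulative arclength along the rasterised chain
      step <- sqrt(rowSums((pts - rbind(soma, pts[-nrow(pts), , drop = FALSE]))^2))
      arc_mm <- cumsum(step) * electrode_pitch_mm
      delay_frames <- arc_mm / velocity_m_s / 1000 * sampling_rate
      path <- data.frame(row = pts[, 1], col = pts[, 2],
                         arc_mm = arc_mm, delay_frames = delay_frames,
                         dist_to_soma = d)
    }
  }
  structure(
    list(soma = soma, path = path, velocity_m_s = velocity_m_s,
         soma_amplitude_uv = soma_amplitude_uv, spatial_sigma = spatial_sigma,
         axon_amplitude_uv = axon_amplitude_uv,
         electrode_pitch_mm = electrode_pitch_mm,
         sampling_rate = sampling_rate),
    class = "synthetic_axon"
  )
}

# Canonical biphasic extracellular spike waveform over the 50-frame window
# (10 pre-spike, 40 post-spike); trough at frame 11, peak magnitude 1.
spike_waveform <- function(n_frames = 50, trough_frame = 11) {
  f <- seq_len(n_frames)
  w <- -exp(-((f - trough_frame)^2) / (2 * 1.6^2)) +
    0.35 * exp(-((f - trough_frame - 5)^2) / (2 * 3.5^2))
  w / max(abs(w))
}

# Noise-free 4096 x 50 footprint template for a synthetic axon. The waveform
# on an axon channel is delayed by arclength / velocity.
footprint_template <- function(axon, n_frames = 50) {
  tmpl <- matrix(0, nrow = 64 * 64, ncol = n_frames)
  w <- spike_waveform(n_frames)
  sig <- axon$spatial_sigma
  # soma with Gaussian spatial decay on a local patch
  r0 <- axon$soma[1]; c0 <- axon$soma[2]
  half <- ceiling(3 * sig)
  for (r in max(1, r0 - half):min(64, r0 + half)) {
    for (cc in max(1, c0 - half):min(64, c0 + half)) {
      g <- exp(-((r - r0)^2 + (cc - c0)^2) / (2 * sig^2))
      ch <- (r - 1) * 64 + cc
      tmpl[ch, ] <- tmpl[ch, ] + axon$soma_amplitude_uv * g * w
    }
  }
  if (!is.null(axon$path)) {
    frac <- seq_len(n_frames)
    for (i in seq_len(nrow(axon$path))) {
      ch <- (axon$path$row[i] - 1) * 64 + axon$path$col[i]
      d <- axon$path$delay_frames[i]
      # linear-interpolated delayed waveform
      src <- frac - d
      wi <- ifelse(src >= 1 & src <= n_frames,
                   stats::approx(seq_len(n_frames), w, xout = pmax(1, pmin(n_frames, src)),
                                 rule = 2)$y, 0)
      wi[src < 1 | src > n_frames] <- 0
      tmpl[ch, ] <- tmpl[ch, ] + axon$axon_amplitude_uv * wi
    }
  }
  tmpl
}

#' Simulate spike-aligned voltage snippets for a synthetic footprint
#'
#' Places the noiseless footprint template (soma waveform with Gaussian
#' spatial decay; axon waveform delayed by arclength / velocity) and adds
#' i.i.d. Gaussian noise per snippet. Snippets are generated lazily: the
#' returned source yields snippet `i` on demand so that large stacks are
#' never held in memory.
#'
#' @param axon A [synthetic_axon()].
#' @param n_spikes Number of snippets (>= 1).
#' @param noise_sd Noise standard deviation, microvolts.
#' @param seed Integer seed; snippet `i` is reproducible as `seed + i`.
#' @return A `snippet_source` with `$snippet(i)` returning a 4096 x 50
#'   matrix, plus the noiseless `$template`.
#' @export
simulate_footprint <- function(axon, n_spikes, noise_sd = 0, seed = 1) {
  stopifnot(n_spikes >= 1)
  tmpl <- footprint_template(axon)
  src <- list(
    template = tmpl,
    n_spikes = n_spikes,
    noise_sd = noise_sd,
    seed = seed,
    sampling_rate = axon$sampling_rate,
    snippet = function(i) {
      if (noise_sd <= 0) return(tmpl)
      old <- withr_seed(seed + i)
      on.exit(restore_seed(old), add = TRUE)
      tmpl + matrix(stats::rnorm(length(tmpl), sd = noise_sd),
                    nrow = nrow(tmpl))
    }
  )
  class(src) <- "snippet_source"
  src
}

# Archetype constructors mirroring the four response groups plus
# stimulus-independent noise cells.
archetype_cell <- function(kind, id) {
  switch(kind,
    off_fast = gt_cell(id, baseline_rate = 1, gain = 120,
                       on_weight = 0.1, off_weight = 0.9,
                       filter_kind = "biphasic", tau_s = 0.012,
                       spectral_weights = c(1, 0.8, 0.6, 0.4, 0.15, 0.02)),
    # fast near-zero-sum chromatic weights plus a slow opposed pathway:
    # colour steps beat white steps, and the kernels are time-dependently
    # opponent (fast and slow lobes of opposite sign per LED)
    # branch weights offset the unequal net weight sums of the two
    # pathways (0.3 vs 0.7) so white steps drive On and Off about equally
    onoff_opponent = gt_cell(id, baseline_rate = 1, gain = 90,
                             on_weight = 0.75, off_weight = 0.25,
                             filter_kind = "biphasic", tau_s = 0.015,
                             spectral_weights = c(1, 0.5, 0, -0.4, -0.7, -0.1),
                             off_pathway = list(weights = c(0.6, 0.4, 0.2, -0.1, -0.4, 0),
                                                tau_s = 0.045,
                                                filter_kind = "biphasic")),
    on_transient_narrow = gt_cell(id, baseline_rate = 0.5, gain = 150,
                                  on_weight = 1, off_weight = 0,
                                  filter_kind = "biphasic", tau_s = 0.012,
                                  # long-wavelength opponent surround narrows
                                  # the tuning and makes colour beat white
                                  spectral_weights = c(-0.4, -0.3, 0, 0.2, 1, 0.1)),
    on_sustained_broad = gt_cell(id, baseline_rate = 1, gain = 35,
                                 on_weight = 1, off_weight = 0,
                                 filter_kind = "monophasic", tau_s = 0.05,
                                 spectral_weights = c(0.7, 0.8, 1, 0.9, 0.8, 0.3)),
    noise = gt_cell(id, baseline_rate = 4, gain = 0),
    stop("unknown archetype: ", kind, call. = FALSE)
  )
}

#' Default fixture configuration
#'
#' @param n_per_archetype Named integer vector of cell counts per archetype.
#' @param n_repeats_steps,n_repeats_chirp Stimulus repeat counts (defaults 5
#'   and 3, matching the recording protocol).
#' @param noise_frames Length of the chromatic noise run (default 18000
#'   frames at 20 Hz).
#' @return A list of configuration values for [generate_fixture_dataset()].
#' @export
fixture_config <- function(n_per_archetype = c(off_fast = 8, onoff_opponent = 8,
                                               on_transient_narrow = 8,
                                               on_sustained_broad = 8, noise = 4),
                           n_repeats_steps = 5, n_repeats_chirp = 3,
                           noise_frames = 18000) {
  list(n_per_archetype = n_per_archetype,
       n_repeats_steps = n_repeats_steps,
       n_repeats_chirp = n_repeats_chirp,
       noise_frames = noise_frames)
}

#' Generate the ground-truth-labelled fixture dataset
#'
#' Builds all four stimulus timelines, instantiates the configured archetype
#' cells, and simulates spike responses to each stimulus. The manifest
#' records every ground-truth parameter for recovery tests.
#'
#' @param config From [fixture_config()].
#' @param seed Integer seed; the dataset is deterministic given it.
#' @return A list: `cells` (gt_cell list), `manifest` (data.frame of
#'   ground-truth parameters), `timelines` (ws, cs, chirp, noise), and
#'   `spikes` (named list of spike tables per stimulus).
#' @export
generate_fixture_dataset <- function(config = fixture_config(), seed = 1) {
  counts <- config$n_per_archetype
  cells <- list()
  manifest <- list()
  for (kind in names(counts)) {
    for (i in seq_len(counts[[kind]])) {
      id <- sprintf("%s_%02d", kind, i)
      cell <- archetype_cell(kind, id)
      cells[[id]] <- cell
      signs <- switch(kind,
        off_fast = c(pi = -1, ti = 1, sd = -1),
        onoff_opponent = c(pi = 0, ti = NA, sd = 1),
        on_transient_narrow = c(pi = 1, ti = 1, sd = 1),
        on_sustained_broad = c(pi = 1, ti = -1, sd = -1),
        noise = c(pi = NA, ti = NA, sd = NA)
      )
      manifest[[id]] <- data.frame(
        cell_id = id, archetype = kind,
        baseline_rate = cell$baseline_rate, gain = cell$gain,
        on_weight = cell$on_weight, off_weight = cell$off_weight,
        filter_kind = cell$filter_kind, tau_s = cell$tau_s,
        opponent = !is.null(cell$opponent),
        expected_pi_sign = signs[["pi"]], expected_ti_sign = signs[["ti"]],
        expected_sd_sign = signs[["sd"]],
        stringsAsFactors = FALSE
      )
    }
  }
  timelines <- list(
    ws = build_white_steps(),
    cs = build_colour_steps(),
    chirp = build_chirp(),
    noise = build_spectral_noise(seed = seed, n_frames = config$noise_frames)
  )
  spikes <- list(
    ws = simulate_lnp(cells, timelines$ws, config$n_repeats_steps, seed = seed + 1),
    cs = simulate_lnp(cells, timelines$cs, config$n_repeats_steps, seed = seed + 2),
    chirp = simulate_lnp(cells, timelines$chirp, config$n_repeats_chirp, seed = seed + 3),
    noise = simulate_lnp(cells, timelines$noise, 1, seed = seed + 4, dt = 0.002)
  )
  list(cells = cells, manifest = do.call(rbind, manifest),
       timelines = timelines, spikes = spikes, seed = seed, config = config)
}
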