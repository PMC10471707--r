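#' @title Electrical images: axon detection, tracing and conduction velocity
#' @name eimage
#' @description
#' An electrical image (EI) is the spike-triggered average of the
#' extracellular voltage on all 4096 channels of the 64 x 64 array, over a
#' window of 10 frames before and 40 frames after each spike. A per-channel
#' signal-strength score isolates channels carrying the cell's signal; the
#' axon, when present, appears as a spatio-temporal wave whose transit time
#' along the shortest path through the retained channels yields the
#' conduction velocity.
NULL

#' Compute an electrical image from spike-aligned voltage snippets
#'
#' @param voltage A `snippet_source` (see [simulate_footprint()]), a list of
#'   4096 x 50 matrices, or a 3-d array (n_spikes x 4096 x 50).
#' @param spikes Optional numeric spike times (seconds); when given together
#'   with `max_time_s`, only snippets of spikes within the first
#'   `max_time_s` seconds are averaged.
#' @param max_time_s Session-time cutoff, seconds (default 1800, the first
#'   half hour).
#' @param n_frames Expected window length (default 50: 10 pre + 40 post).
#' @return An `electrical_image`: list with `stas` (4096 x 50 matrix of
#'   per-channel voltage averages), `n_spikes`, `sampling_rate`.
#' @export
compute_ei <- function(voltage, spikes = NULL, max_time_s = 1800,
                       n_frames = 50) {
  if (inherits(voltage, "snippet_source")) {
    idx <- seq_len(voltage$n_spikes)
    if (!is.null(spikes)) {
      stopifnot(length(spikes) == voltage$n_spikes)
      idx <- idx[spikes <= max_time_s]
    }
    if (!length(idx)) stop("no usable spikes for the EI", call. = FALSE)
    acc <- matrix(0, nrow = nrow(voltage$template), ncol = n_frames)
    for (i in idx) acc <- acc + voltage$snippet(i)
    stas <- acc / length(idx)
    fs <- voltage$sampling_rate
    n_used <- length(idx)
  } else if (is.list(voltage)) {
    if (!length(voltage)) stop("no usable spikes for the EI", call. = FALSE)
    acc <- Reduce(`+`, voltage)
    stas <- acc / length(voltage)
    fs <- 18000
    n_used <- length(voltage)
  } else {
    stopifnot(is.array(voltage), length(dim(voltage)) == 3)
    if (dim(voltage)[1] == 0) stop("no usable spikes for the EI", call. = FALSE)
    stas <- apply(voltage, c(2, 3), mean)
    fs <- 18000
    n_used <- dim(voltage)[1]
  }
  stopifnot(ncol(stas) == n_frames)
  structure(list(stas = stas, n_spikes = n_used, sampling_rate = fs),
            class = "electrical_image")
}

#' Per-channel signal-strength map of an electrical image
#'
#' Scores each channel as `max(STA) * |min(STA)| * diff(STA)`, with the
#' first difference reduced to its maximum absolute value (steepest slope);
#' with `literal_sign = TRUE` the raw signed product `max * min * diff` is
#' used instead. Scores are median-subtracted across channels; channels at
#' or below zero are dropped, surviving channels with no surviving
#' 8-neighbour are dropped, and the map is flagged rejected when more than
#' `max_channels` channels survive.
#'
#' @param ei An `electrical_image`.
#' @param diff_stat `"max_abs"` (default) or `"total_variation"`
#'   scalarisation of the first difference.
#' @param literal_sign Use the literal signed product (default FALSE).
#' @param max_channels Rejection bound on surviving channels (default 400).
#' @return An `esignal_map`: list with `scores` (64 x 64), `mask` (64 x 64
#'   logical), `rejected`.
#' @export
compute_esignal <- function(ei, diff_stat = c("max_abs", "total_variation"),
                            literal_sign = FALSE, max_channels = 400) {
  diff_stat <- match.arg(diff_stat)
  stas <- ei$stas
  mx <- apply(stas, 1, max)
  mn <- apply(stas, 1, min)
  dd <- stas[, -1, drop = FALSE] - stas[, -ncol(stas), drop = FALSE]
  dscal <- if (diff_stat == "max_abs") apply(abs(dd), 1, max) else rowSums(abs(dd))
  scores <- if (literal_sign) mx * mn * dscal else mx * abs(mn) * dscal
  scores <- scores - stats::median(scores)
  # retained channels must clear both the median (score > 0) and the array
  # mean (z-score > 0): the score distribution is heavy-tailed, so the mean
  # sits far above the median and isolates the signal-bearing channels
  sdev <- stats::sd(scores)
  z <- if (sdev > 0) (scores - mean(scores)) / sdev else scores * 0
  keep <- scores > 0 & z > 0
  score_mat <- matrix(scores, nrow = 64, ncol = 64, byrow = TRUE)
  keep_mat <- matrix(keep, nrow = 64, ncol = 64, byrow = TRUE)
  # drop isolated survivors (no surviving 8-neighbour)
  if (any(keep_mat)) {
    padded <- matrix(FALSE, 66, 66)
    padded[2:65, 2:65] <- keep_mat
    neigh <- matrix(0L, 64, 64)
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      neigh <- neigh + padded[2:65 + dr, 2:65 + dc]
    }
    keep_mat <- keep_mat & neigh > 0
  }
  structure(
    list(scores = score_mat, mask = keep_mat,
         rejected = sum(keep_mat) > max_channels),
    class = "esignal_map"
  )
}

# channel (row, col) -> linear index, row-major to match compute_esignal
chan_index <- function(row, col) (row - 1L) * 64L + col

#' Trace the axon of an electrical image
#'
#' The channel with the highest signal score is the spatial origin of the
#' spike; the frame of its STA minimum is the temporal origin. Retained
#' channels within `soma_radius` channels of the origin are treated as soma
#' and excluded. The remaining channels form a geometric proximity graph
#' (edges between channels closer than `graph_radius` pitches); the axon is
#' the shortest path from the channel nearest the soma to the channel whose
#' STA minimum occurs latest.
#'
#' @param ei An `electrical_image`.
#' @param esignal An `esignal_map` from [compute_esignal()].
#' @param soma_radius Soma exclusion radius, channels (default 6).
#' @param graph_radius Proximity-graph connection radius, channel pitches
#'   (default 2.2: connects diagonal neighbours and single-channel gaps in
#'   fractionated, saltatory footprints).
#' @param min_path_channels Minimum number of path channels for a detected
#'   axon (default 10).
#' @param electrode_pitch_mm Electrode pitch, mm (default 0.042).
#' @return An `axon_trace`: soma channel and frame, terminal channel and
#'   frame, path (data.frame row/col), `d_short_mm`, `fmin_max` (frames
#'   relative to the temporal origin), `detected`.
#' @export
trace_axon <- function(ei, esignal, soma_radius = 6, graph_radius = 2.2,
                       min_path_channels = 10, electrode_pitch_mm = 0.042) {
  if (esignal$rejected) stop("esignal map is rejected", call. = FALSE)
  mask <- esignal$mask
  empty <- function(reason) {
    structure(list(soma = c(NA, NA), soma_frame = NA, terminal = c(NA, NA),
                   terminal_frame = NA, path = NULL, d_short_mm = 0,
                   fmin_max = NA, detected = FALSE, reason = reason),
              class = "axon_trace")
  }
  if (!any(mask)) return(empty("empty mask"))
  scores <- esignal$scores
  scores[!mask] <- -Inf
  o <- arrayInd(which.max(scores), dim(scores))
  soma <- c(o[1], o[2])
  soma_sta <- ei$stas[chan_index(soma[1], soma[2]), ]
  fmin0 <- which.min(soma_sta)
  ch <- which(mask, arr.ind = TRUE)
  d_soma <- sqrt((ch[, 1] - soma[1])^2 + (ch[, 2] - soma[2])^2)
  far <- d_soma > soma_radius
  if (sum(far) < 2) return(empty("no channels beyond soma"))
  ch <- ch[far, , drop = FALSE]
  d_soma <- d_soma[far]
  fmin <- apply(ei$stas[chan_index(ch[, 1], ch[, 2]), , drop = FALSE], 1, which.min)
  ord <- order(fmin)
  ch <- ch[ord, , drop = FALSE]
  fmin <- fmin[ord]
  d_soma <- d_soma[ord]
  # geometric proximity graph, edge weight = Euclidean distance in pitches
  n <- nrow(ch)
  dm <- as.matrix(stats::dist(ch))
  adj <- dm <= graph_radius & dm > 0
  el <- which(adj & upper.tri(adj), arr.ind = TRUE)
  if (!nrow(el)) return(empty("no edges in proximity graph"))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  igraph::E(g)$weight <- dm[el]
  from <- which.min(d_soma)          # channel nearest the soma
  to <- which.max(fmin)              # latest STA minimum = axon terminal
  sp <- suppressWarnings(
    igraph::shortest_paths(g, from = from, to = to, weights = igraph::E(g)$weight,
                           output = "both")
  )
  if (!length(sp$vpath[[1]])) return(empty("terminal unreachable"))
  vp <- as.integer(sp$vpath[[1]])
  # path length from the signal origin: soma-to-start hop plus graph path
  path_len <- d_soma[from] + sum(igraph::E(g)$weight[as.integer(sp$epath[[1]])])
  d_short <- path_len * electrode_pitch_mm
  fmin_max_abs <- fmin[to]
  structure(
    list(soma = soma, soma_frame = fmin0,
         terminal = c(ch[to, 1], ch[to, 2]), terminal_frame = fmin_max_abs,
         path = data.frame(row = ch[vp, 1], col = ch[vp, 2], fmin = fmin[vp]),
         d_short_mm = d_short,
         fmin_max = fmin_max_abs - fmin0,
         detected = length(vp) >= min_path_channels,
         reason = NULL),
    class = "axon_trace"
  )
}

#' Axonal conduction velocity from a trace
#'
#' `S_axon = D_short / (Fmin_max * period) / 1000`, with `D_short` the path
#' length in mm, `Fmin_max` the transit time in frames from the temporal
#' origin to the path terminal, and `period` the sampling interval; the
#' result is in m/s.
#'
#' @param trace An `axon_trace` with `detected = TRUE`.
#' @param sampling_rate Sampling frequency, Hz (default 18000).
#' @return Velocity in m/s.
#' @export
conduction_velocity <- function(trace, sampling_rate = 18000) {
  if (!isTRUE(trace$detected)) stop("axon not detected", call. = FALSE)
  if (trace$d_short_mm == 0) return(0)
  if (is.na(trace$fmin_max) || trace$fmin_max <= 0) {
    stop("undefined velocity: non-positive transit time", call. = FALSE)
  }
  trace$d_short_mm / (trace$fmin_max / sampling_rate) / 1000
}

#' Fit the axon-detection saturation curve
#'
#' Bins cells by spike count and fits `f(n) = A (1 - exp(-n / k))` to the
#' per-bin detected fraction by least squares, estimating the asymptotic
#' fraction of cells with a detectable axon.
#'
#' @param n_spikes Integer vector of spike counts per cell.
#' @param detected Logical vector, axon detected per cell.
#' @param n_bins Number of spike-count bins (default 10, quantile-spaced).
#' @return List with `asymptote` (A, in [0, 1]), `rate_constant` (k),
#'   `bins` (data.frame n, fraction), `fit_ok`.
#' @export
fit_axon_detection_asymptote <- function(n_spikes, detected, n_bins = 10) {
  stopifnot(length(n_spikes) == length(detected))
  qs <- unique(stats::quantile(n_spikes, probs = seq(0, 1, length.out = n_bins + 1)))
  if (length(qs) < 4) stop("need at least 3 spike-count bins", call. = FALSE)
  grp <- cut(n_spikes, qs, include.lowest = TRUE)
  bins <- data.frame(
    n = tapply(n_spikes, grp, stats::median),
    fraction = tapply(as.numeric(detected), grp, mean)
  )
  bins <- bins[stats::complete.cases(bins), ]
  if (all(bins$fraction == bins$fraction[1])) {
    return(list(asymptote = bins$fraction[1], rate_constant = NA_real_,
                bins = bins, fit_ok = FALSE))
  }
  fit <- tryCatch(
    stats::nls(fraction ~ A * (1 - exp(-n / k)), data = bins,
               start = list(A = max(bins$fraction), k = stats::median(bins$n)),
               algorithm = "port", lower = c(A = 0, k = 1e-6),
               upper = c(A = 1, k = Inf)),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(list(asymptote = mean(detected), rate_constant = NA_real_,
                bins = bins, fit_ok = FALSE))
  }
  cf <- stats::coef(fit)
  list(asymptote = unname(cf["A"]), rate_constant = unname(cf["k"]),
       bins = bins, fit_ok = TRUE)
}
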