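#' @title Stimulus timelines for full-field chromatic MEA experiments
#' @name stimgen
#' @description
#' Constructors for the four full-field stimuli used to characterise retinal
#' ganglion cell responses: achromatic contrast steps ("white steps", WS),
#' single-LED colour steps (CS), an exponentially accelerating chirp, and a
#' binary chromatic noise sequence on four of the six LEDs. Timelines carry a
#' frame-level LED intensity matrix plus epoch annotations consumed by the
#' response analyses.
NULL

#' Default LED specification table
#'
#' The six-LED stimulator set spanning the chick's spectral range, with
#' centre wavelengths and calibrated powers.
#'
#' @return A data.frame with columns `name`, `wavelength_nm`, `power_nw`,
#'   ordered red to UV (R, Y, G, C, B, U).
#' @export
led_specs <- function() {
  data.frame(
    name = c("R", "Y", "G", "C", "B", "U"),
    wavelength_nm = c(630, 560, 505, 480, 420, 360),
    power_nw = c(100, 59, 65, 60, 65, 20),
    stringsAsFactors = FALSE
  )
}

new_timeline <- function(frames, epochs, frame_rate, leds = led_specs()) {
  stopifnot(is.matrix(frames), ncol(frames) == nrow(leds))
  if (any(frames < 0 | frames > 1)) {
    stop("LED intensities must lie in [0, 1]", call. = FALSE)
  }
  colnames(frames) <- leds$name
  structure(
    list(
      frames = frames,
      epochs = epochs,
      frame_rate = frame_rate,
      leds = leds,
      duration_s = nrow(frames) / frame_rate
    ),
    class = "stimulus_timeline"
  )
}

#' @export
print.stimulus_timeline <- function(x, ...) {
  kinds <- paste(unique(x$epochs$kind), collapse = ", ")
  cat(sprintf(
    "<stimulus_timeline> %d frames @ %g Hz (%.1f s), epochs: %s\n",
    nrow(x$frames), x$frame_rate, x$duration_s, kinds
  ))
  invisible(x)
}

epoch_row <- function(kind, start, end, parameter) {
  data.frame(kind = kind, start_s = start, end_s = end,
             parameter = parameter, stringsAsFactors = FALSE)
}

#' Build the white-step (WS) contrast series
#'
#' All six LEDs are driven together in 2 s On / 2 s Off square steps at a
#' descending series of contrasts (defaults 100% down to 10% in 10% steps).
#'
#' @param contrasts Numeric vector of step contrasts in (0, 1], one On/Off
#'   cycle per entry. Default `seq(1, 0.1, by = -0.1)`.
#' @param on_s,off_s On and Off durations in seconds (default 2 each).
#' @param frame_rate Stimulator frame rate in Hz (default 60).
#' @return A `stimulus_timeline` with `WS_on`/`WS_off` epochs; the epoch
#'   `parameter` records the contrast.
#' @export
build_white_steps <- function(contrasts = seq(1, 0.1, by = -0.1),
                              on_s = 2, off_s = 2, frame_rate = 60) {
  if (length(contrasts) < 1 || any(contrasts <= 0) || any(contrasts > 1)) {
    stop("contrasts must lie in (0, 1]", call. = FALSE)
  }
  stopifnot(on_s > 0, off_s > 0)
  n_on <- round(on_s * frame_rate)
  n_off <- round(off_s * frame_rate)
  frames <- matrix(0, nrow = (n_on + n_off) * length(contrasts), ncol = 6)
  epochs <- vector("list", 2L * length(contrasts))
  t0 <- 0
  row0 <- 0L
  for (k in seq_along(contrasts)) {
    frames[row0 + seq_len(n_on), ] <- contrasts[k]
    epochs[[2 * k - 1]] <- epoch_row("WS_on", t0, t0 + on_s, contrasts[k])
    epochs[[2 * k]] <- epoch_row("WS_off", t0 + on_s, t0 + on_s + off_s,
                                 contrasts[k])
    t0 <- t0 + on_s + off_s
    row0 <- row0 + n_on + n_off
  }
  new_timeline(frames, do.call(rbind, epochs), frame_rate)
}

#' Build the colour-step (CS) series
#'
#' Each LED is driven individually at full power in a 2 s On / 2 s Off cycle,
#' by default in the order R, Y, G, C, B, U (630 to 360 nm).
#'
#' @param order Character vector of LED names, a subset or permutation of
#'   `led_specs()$name`, one On/Off cycle per entry.
#' @param on_s,off_s On/Off durations in seconds.
#' @param frame_rate Stimulator frame rate in Hz (default 60).
#' @return A `stimulus_timeline` with `CS_on`/`CS_off` epochs; the epoch
#'   `parameter` records the LED wavelength in nm.
#' @export
build_colour_steps <- function(order = led_specs()$name,
                               on_s = 2, off_s = 2, frame_rate = 60) {
  leds <- led_specs()
  if (anyDuplicated(order) || !all(order %in% leds$name)) {
    stop("order must be distinct LED names from led_specs()", call. = FALSE)
  }
  n_on <- round(on_s * frame_rate)
  n_off <- round(off_s * frame_rate)
  frames <- matrix(0, nrow = (n_on + n_off) * length(order), ncol = 6)
  epochs <- vector("list", 2L * length(order))
  t0 <- 0
  row0 <- 0L
  for (k in seq_along(order)) {
    led_idx <- match(order[k], leds$name)
    wl <- leds$wavelength_nm[led_idx]
    frames[row0 + seq_len(n_on), led_idx] <- 1
    epochs[[2 * k - 1]] <- epoch_row("CS_on", t0, t0 + on_s, wl)
    epochs[[2 * k]] <- epoch_row("CS_off", t0 + on_s, t0 + on_s + off_s, wl)
    t0 <- t0 + on_s + off_s
    row0 <- row0 + n_on + n_off
  }
  new_timeline(frames, do.call(rbind, epochs), frame_rate)
}

#' Instantaneous frequency and phase of the exponential chirp
#'
#' The chirp accelerates exponentially: f(t) = f0 (f1/f0)^(t/T), with
#' closed-form phase phi(t) = 2 pi f0 T / ln(f1/f0) ((f1/f0)^(t/T) - 1).
#'
#' @param t Time(s) in seconds from chirp onset.
#' @param f0,f1 Start and end frequencies in Hz.
#' @param T_s Sweep duration in seconds.
#' @return For `chirp_frequency`, Hz; for `chirp_phase`, radians.
#' @export
chirp_frequency <- function(t, f0 = 1, f1 = 30, T_s = 30) {
  f0 * (f1 / f0)^(t / T_s)
}

#' @rdname chirp_frequency
#' @export
chirp_phase <- function(t, f0 = 1, f1 = 30, T_s = 30) {
  k <- log(f1 / f0)
  2 * pi * f0 * T_s / k * ((f1 / f0)^(t / T_s) - 1)
}

#' Build the chirp stimulus
#'
#' A full-contrast "white" sinusoidal flicker on all six LEDs whose frequency
#' accelerates exponentially from `f0` to `f1` over `T_s` seconds. Intensity
#' is 0.5 + 0.5 sin(phi(t)), so phase 0 (mod 2 pi) marks the On onset and
#' phase pi the Off onset.
#'
#' @param f0,f1 Start/end frequency, Hz; defaults 1 and 30.
#' @param T_s Duration, seconds; default 30.
#' @param frame_rate Stimulator frame rate in Hz (default 60).
#' @return A `stimulus_timeline` with one `chirp` epoch; the `phase` element
#'   stores the instantaneous phase (radians) per frame.
#' @export
build_chirp <- function(f0 = 1, f1 = 30, T_s = 30, frame_rate = 60) {
  if (f0 <= 0 || f1 <= f0 || T_s <= 0) {
    stop("require 0 < f0 < f1 and T_s > 0", call. = FALSE)
  }
  n <- round(T_s * frame_rate)
  t <- (seq_len(n) - 1) / frame_rate
  phi <- chirp_phase(t, f0, f1, T_s)
  intensity <- 0.5 + 0.5 * sin(phi)
  frames <- matrix(rep(intensity, 6), ncol = 6)
  tl <- new_timeline(frames, epoch_row("chirp", 0, T_s, NA_real_), frame_rate)
  tl$phase <- phi
  tl$chirp_pars <- list(f0 = f0, f1 = f1, T_s = T_s)
  tl
}

# Maximal-length binary sequence from the two-term recurrence
# a[i] = a[i-lag] XOR a[i-order] of a primitive trinomial; period 2^order - 1.
lfsr_sequence <- function(n, order, lag, init) {
  a <- integer(n + order)
  a[seq_len(order)] <- init
  for (i in (order + 1):(n + order)) {
    a[i] <- (a[i - lag] + a[i - order]) %% 2L
  }
  a[(order + 1):(n + order)]
}

# Primitive trinomials x^order + x^lag + 1 (or reciprocal).
.lfsr_taps <- list(`7` = 1L, `10` = 3L, `11` = 2L, `15` = 1L)

#' Build the binary chromatic noise sequence
#'
#' Four LEDs (R, G, C, B) flicker independently in binary pseudorandom
#' sequences at 20 Hz; the default run length is 18,000 frames. Each LED's
#' column is generated by a maximal-length linear-feedback shift register
#' (an M-sequence) whose initial state derives from `seed`, or by i.i.d.
#' Bernoulli(0.5) draws when `method = "bernoulli"`.
#'
#' @param seed Integer seed; the sequence is reproducible from it.
#' @param frame_rate Frames per second (default 20).
#' @param n_frames Number of frames (default 18000).
#' @param method `"mseq"` (default) for LFSR M-sequences, `"bernoulli"` for
#'   i.i.d. fair coin flips.
#' @param order LFSR register length (default 15; period 2^order - 1).
#' @return A `noise_sequence`: list with binary `values`
#'   (n_frames x 4, columns R, G, C, B), `frame_rate`, `seed`, `times_s`.
#' @export
build_spectral_noise <- function(seed = 1, frame_rate = 20, n_frames = 18000,
                                 method = c("mseq", "bernoulli"), order = 15) {
  method <- match.arg(method)
  stopifnot(n_frames > 0)
  led_names <- c("R", "G", "C", "B")
  values <- matrix(0L, nrow = n_frames, ncol = 4,
                   dimnames = list(NULL, led_names))
  if (method == "bernoulli") {
    old <- withr_seed(seed)
    on.exit(restore_seed(old), add = TRUE)
    values[] <- as.integer(stats::runif(n_frames * 4) < 0.5)
  } else {
    lag <- .lfsr_taps[[as.character(order)]]
    if (is.null(lag)) stop("unsupported LFSR order", call. = FALSE)
    old <- withr_seed(seed)
    on.exit(restore_seed(old), add = TRUE)
    for (j in 1:4) {
      state <- integer(order)
      while (all(state == 0L)) {
        state <- as.integer(stats::runif(order) < 0.5)
      }
      values[, j] <- lfsr_sequence(n_frames, order, lag, state)
    }
  }
  structure(
    list(values = values, frame_rate = frame_rate, seed = seed,
         n_frames = n_frames, method = method,
         times_s = (seq_len(n_frames) - 1) / frame_rate),
    class = "noise_sequence"
  )
}

#' @export
print.noise_sequence <- function(x, ...) {
  cat(sprintf("<noise_sequence> %d frames @ %g Hz, %s, seed %d\n",
              x$n_frames, x$frame_rate, x$method, x$seed))
  invisible(x)
}

# Seed helpers: set a local RNG seed, returning the previous state.
withr_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

#' Write / read a stimulus timeline as plain text
#'
#' Serialises the frame matrix and epoch table to a pair of CSV files with
#' full floating-point precision, so that a timeline round-trips exactly.
#'
#' @param timeline A `stimulus_timeline`.
#' @param path Base path; `<path>_frames.csv` and `<path>_epochs.csv` are
#'   written.
#' @return `write_timeline` returns `path` invisibly; `read_timeline` a
#'   `stimulus_timeline`.
#' @export
write_timeline <- function(timeline, path) {
  frames <- as.data.frame(timeline$frames)
  utils::write.csv(
    data.frame(lapply(frames, function(col) sprintf("%.17g", col)),
               check.names = FALSE),
    paste0(path, "_frames.csv"), row.names = FALSE, quote = FALSE
  )
  ep <- timeline$epochs
  ep$start_s <- sprintf("%.17g", ep$start_s)
  ep$end_s <- sprintf("%.17g", ep$end_s)
  ep$parameter <- sprintf("%.17g", ep$parameter)
  ep$frame_rate <- timeline$frame_rate
  utils::write.csv(ep, paste0(path, "_epochs.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_timeline
#' @export
read_timeline <- function(path) {
  frames <- as.matrix(utils::read.csv(paste0(path, "_frames.csv")))
  ep <- utils::read.csv(paste0(path, "_epochs.csv"), stringsAsFactors = FALSE)
  frame_rate <- ep$frame_rate[1]
  ep$frame_rate <- NULL
  new_timeline(frames, ep, frame_rate)
}

#' Check that epoch annotations tile a timeline without gaps or overlaps
#'
#' @param timeline A `stimulus_timeline`.
#' @return TRUE if consecutive epochs abut exactly and span [0, duration].
#' @export
epochs_tile <- function(timeline) {
  ep <- timeline$epochs
  isTRUE(all.equal(ep$start_s[1], 0)) &&
    isTRUE(all.equal(ep$end_s[nrow(ep)], timeline$duration_s)) &&
    (nrow(ep) == 1 ||
       isTRUE(all.equal(ep$start_s[-1], ep$end_s[-nrow(ep)])))
}
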