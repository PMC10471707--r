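#' @title ISI-distance and SPIKE-synchronization profiles
#' @name spikedist
#' @description
#' Parameter-free spike-train dissimilarity measures used by the step-response
#' quality index. The ISI-distance profile compares the instantaneous
#' interspike intervals of train pairs; SPIKE-synchronization counts
#' coincident spikes within an adaptive window of half the surrounding
#' interspike intervals. Both follow the standard published definitions, with
#' auxiliary-interval edge correction.
NULL

# Instantaneous ISI x(t) of one train at query times; edge intervals use
# max(edge length, adjacent ISI) as their estimate.
.isi_at <- function(spikes, t_start, t_end, times) {
  spikes <- sort(spikes[spikes >= t_start & spikes <= t_end])
  n <- length(spikes)
  if (n == 0) return(rep(t_end - t_start, length(times)))
  isis <- if (n >= 2) diff(spikes) else numeric(0)
  first <- if (n >= 2) max(spikes[1] - t_start, isis[1]) else
    max(spikes[1] - t_start, t_end - spikes[n])
  last <- if (n >= 2) max(t_end - spikes[n], isis[n - 1]) else first
  vals <- c(first, isis, last)
  idx <- findInterval(times, spikes) + 1L
  vals[idx]
}

#' Multivariate ISI-distance profile
#'
#' Average over all train pairs of `|x_i(t) - x_j(t)| / max(x_i(t), x_j(t))`,
#' where `x(t)` is the instantaneous interspike interval. 0 for identical
#' trains, approaching 1 for very dissimilar rates. A pair with an empty
#' train contributes 1 by convention.
#'
#' @param trains List of numeric spike-time vectors.
#' @param t_start,t_end Observation interval, seconds.
#' @param times Query times (default 1000 regular samples).
#' @return data.frame with `time` and profile `value`.
#' @export
isi_profile <- function(trains, t_start, t_end,
                        times = seq(t_start, t_end, length.out = 1000)) {
  stopifnot(length(trains) >= 2)
  np <- 0L
  acc <- numeric(length(times))
  xs <- lapply(trains, .isi_at, t_start = t_start, t_end = t_end, times = times)
  empt <- vapply(trains, function(s) sum(s >= t_start & s <= t_end) == 0, logical(1))
  for (i in seq_along(trains)[-length(trains)]) {
    for (j in (i + 1):length(trains)) {
      np <- np + 1L
      if (empt[i] || empt[j]) {
        acc <- acc + 1
      } else {
        acc <- acc + abs(xs[[i]] - xs[[j]]) / pmax(xs[[i]], xs[[j]])
      }
    }
  }
  data.frame(time = times, value = acc / np)
}

# Coincidence values of spikes of train i against train j, adaptive window
# tau = min of the four surrounding ISIs / 2.
.sync_pair <- function(si, sj, t_start, t_end) {
  si <- sort(si); sj <- sort(sj)
  if (!length(si)) return(numeric(0))
  if (!length(sj)) return(rep(0, length(si)))
  surround <- function(s, k) {
    # ISIs before and after spike k of train s (Inf at the edges)
    prev <- if (k > 1) s[k] - s[k - 1] else Inf
    nxt <- if (k < length(s)) s[k + 1] - s[k] else Inf
    c(prev, nxt)
  }
  out <- numeric(length(si))
  for (k in seq_along(si)) {
    jn <- which.min(abs(sj - si[k]))
    tau <- 0.5 * min(c(surround(si, k), surround(sj, jn)))
    out[k] <- as.numeric(abs(sj[jn] - si[k]) < tau)
  }
  out
}

#' Multivariate SPIKE-synchronization profile
#'
#' For every spike of every train, the fraction of other trains containing a
#' coincident spike, where coincidence uses the adaptive window of half the
#' minimum surrounding interspike interval. 1 everywhere for identical
#' trains; near 0 for independent trains.
#'
#' @inheritParams isi_profile
#' @return data.frame with `time` (spike time), `train`, and coincidence
#'   `value` in [0, 1], ordered by time.
#' @export
spike_sync_profile <- function(trains, t_start, t_end) {
  stopifnot(length(trains) >= 2)
  trains <- lapply(trains, function(s) sort(s[s >= t_start & s <= t_end]))
  rows <- list()
  for (i in seq_along(trains)) {
    if (!length(trains[[i]])) next
    acc <- numeric(length(trains[[i]]))
    for (j in seq_along(trains)[-i]) {
      acc <- acc + .sync_pair(trains[[i]], trains[[j]], t_start, t_end)
    }
    rows[[length(rows) + 1]] <- data.frame(
      time = trains[[i]], train = i, value = acc / (length(trains) - 1)
    )
  }
  if (!length(rows)) {
    return(data.frame(time = numeric(0), train = integer(0), value = numeric(0)))
  }
  out <- do.call(rbind, rows)
  out[order(out$time), , drop = FALSE]
}
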