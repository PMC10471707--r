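# Brute-force reference implementations, kept deliberately naive and
# independent of the package's vectorised code paths.

# Instantaneous ISI of one train at a single time, with max(edge, adjacent)
# edge correction.
oracle_isi_at <- function(spikes, t_start, t_end, t) {
  spikes <- sort(spikes)
  n <- length(spikes)
  if (n == 0) return(t_end - t_start)
  isis <- diff(spikes)
  k <- sum(spikes <= t)  # interval index: 0 = before first spike
  if (k == 0) {
    if (n >= 2) max(spikes[1] - t_start, isis[1]) else
      max(spikes[1] - t_start, t_end - spikes[n])
  } else if (k == n) {
    if (n >= 2) max(t_end - spikes[n], isis[n - 1]) else
      max(spikes[1] - t_start, t_end - spikes[n])
  } else {
    spikes[k + 1] - spikes[k]
  }
}

# Pairwise ISI-distance profile value at time t.
oracle_isi_pair <- function(s1, s2, t_start, t_end, t) {
  x1 <- oracle_isi_at(s1, t_start, t_end, t)
  x2 <- oracle_isi_at(s2, t_start, t_end, t)
  abs(x1 - x2) / max(x1, x2)
}

# Coincidence indicator for spike k of train si against train sj, with the
# adaptive window of half the minimum surrounding ISI.
oracle_sync_value <- function(si, sj, k) {
  si <- sort(si); sj <- sort(sj)
  if (!length(sj)) return(0)
  jn <- which.min(abs(sj - si[k]))
  isis <- c(
    if (k > 1) si[k] - si[k - 1] else Inf,
    if (k < length(si)) si[k + 1] - si[k] else Inf,
    if (jn > 1) sj[jn] - sj[jn - 1] else Inf,
    if (jn < length(sj)) sj[jn + 1] - sj[jn] else Inf
  )
  as.numeric(abs(sj[jn] - si[k]) < 0.5 * min(isis))
}

# A small shared fixture dataset, built once per test session.
small_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- fixture_config(
        n_per_archetype = c(off_fast = 4, onoff_opponent = 4,
                            on_transient_narrow = 4, on_sustained_broad = 4,
                            noise = 2),
        noise_frames = 12000
      )
      cache <<- generate_fixture_dataset(cfg, seed = 42)
    }
    cache
  }
})
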