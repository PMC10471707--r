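# Internal numerical helpers shared across modules.

# Causal FIR convolution: y[t] = sum_j k[j] * x[t - j + 1], same length as x.
# FFT-based with padding to a highly composite length.
conv_causal <- function(x, k) {
  n <- length(x)
  m <- length(k)
  nn <- stats::nextn(n + m - 1)
  fx <- stats::fft(c(x, numeric(nn - n)))
  fk <- stats::fft(c(k, numeric(nn - m)))
  Re(stats::fft(fx * fk, inverse = TRUE))[seq_len(n)] / nn
}

# Centred box smoothing with edge truncation (window in samples).
box_smooth <- function(x, width) {
  if (width <= 1) return(x)
  k <- rep(1 / width, width)
  y <- stats::filter(x, k, sides = 2)
  # renormalise truncated edges
  ones <- stats::filter(rep(1, length(x)), k, sides = 2)
  y <- as.numeric(y) / as.numeric(ones)
  idx <- is.na(y)
  y[idx] <- x[idx]
  y
}

# Zero-order-hold lookup of a frame matrix at arbitrary times.
sample_frames <- function(frames, frame_rate, times) {
  idx <- pmin(pmax(floor(times * frame_rate) + 1L, 1L), nrow(frames))
  frames[idx, , drop = FALSE]
}

# Map absolute spike times onto the first-repeat interval [0, duration).
map_to_first_repeat <- function(times, duration) {
  times %% duration
}
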