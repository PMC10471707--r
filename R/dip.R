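#' @title Hartigan's dip statistic for unimodality
#' @name dip
#' @description
#' The dip of a sample is the largest discrepancy between its empirical
#' distribution function and the closest unimodal distribution function:
#' formally, half the maximum distance between the greatest convex minorant
#' and the least concave majorant of the empirical cdf over the modal
#' interval, refined iteratively as in the original algorithm. Used to test
#' spike-waveform PC1 loadings for unimodality, with p-values from a
#' uniform-null bootstrap.
NULL

# Lower ("gcm") or upper ("lcm") convex hull vertex indices of the points
# (x[i], i), i in lo..hi, x sorted non-decreasing. Monotone-chain.
.hull_indices <- function(x, lo, hi, upper = FALSE) {
  idx <- lo:hi
  sgn <- if (upper) -1 else 1
  out <- integer(0)
  for (i in idx) {
    while (length(out) >= 2) {
      a <- out[length(out) - 1]
      b <- out[length(out)]
      # cross product of (a->b) x (a->i) on points (x, index)
      cr <- (x[b] - x[a]) * (i - a) - (b - a) * (x[i] - x[a])
      if (sgn * cr <= 0) out <- out[-length(out)] else break
    }
    out <- c(out, i)
  }
  out
}

# Evaluate the piecewise-linear hull curve at x0. Vertical (tied-x) segments
# take the min for the lower hull and max for the upper.
.hull_value <- function(x, verts, x0, upper = FALSE) {
  vx <- x[verts]
  if (x0 <= vx[1]) {
    at <- verts[vx == vx[1]]
    return(if (upper) max(at) else min(at))
  }
  if (x0 >= vx[length(vx)]) {
    at <- verts[vx == vx[length(vx)]]
    return(if (upper) max(at) else min(at))
  }
  j <- findInterval(x0, vx)
  x1 <- vx[j]; x2 <- vx[j + 1]
  y1 <- verts[j]; y2 <- verts[j + 1]
  if (x2 == x1) return(if (upper) max(y1, y2) else min(y1, y2))
  y1 + (y2 - y1) * (x0 - x1) / (x2 - x1)
}

#' Dip statistic of a numeric sample
#'
#' @param x Numeric vector (n >= 2 for a meaningful value).
#' @return The dip, in [1/(2n), 1/4]; 0 for constant or length-one input.
#' @export
dip_statistic <- function(x) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  if (n < 2 || x[1] == x[n]) return(0)
  low <- 1L
  high <- n
  D <- 1  # count units; minimum attainable discrepancy
  for (iter in 1:100) {
    gcm <- .hull_indices(x, low, high, upper = FALSE)
    lcm <- .hull_indices(x, low, high, upper = TRUE)
    # largest distance between the two hull curves, measured at vertices
    d_best <- -Inf
    side <- "g"
    v_best <- low
    for (v in gcm) {
      dv <- .hull_value(x, lcm, x[v], upper = TRUE) - v + 1
      if (dv > d_best) { d_best <- dv; side <- "g"; v_best <- v }
    }
    for (w in lcm) {
      dw <- w - .hull_value(x, gcm, x[w], upper = FALSE)
      if (dw > d_best) { d_best <- dw; side <- "l"; v_best <- w }
    }
    if (d_best <= D) break
    # modal interval achieving the maximum
    if (side == "g") {
      new_low <- v_best
      later <- lcm[x[lcm] >= x[v_best]]
      new_high <- if (length(later)) min(later) else high
    } else {
      new_high <- v_best
      earlier <- gcm[x[gcm] <= x[v_best]]
      new_low <- if (length(earlier)) max(earlier) else low
    }
    if (new_low < low) new_low <- low
    if (new_high > high) new_high <- high
    # discrepancy of the empirical cdf from the gcm left of the modal
    # interval and from the lcm right of it
    dl <- 0
    if (new_low > low) {
      for (j in low:new_low) {
        g <- .hull_value(x, gcm, x[j], upper = FALSE)
        dl <- max(dl, j - g, g - (j - 1))
      }
    }
    du <- 0
    if (new_high < high) {
      for (j in new_high:high) {
        l <- .hull_value(x, lcm, x[j], upper = TRUE)
        du <- max(du, l - (j - 1), j - l)
      }
    }
    D <- max(D, dl, du)
    if (new_low == low && new_high == high) break
    low <- new_low
    high <- new_high
    if (high - low < 1) break
  }
  max(D, d_best) / (2 * n)
}

#' Dip test p-value by uniform-null bootstrap
#'
#' @param x Numeric sample.
#' @param n_boot Number of uniform-null bootstrap samples (default 1000).
#' @param seed Integer seed for the bootstrap.
#' @return List with `dip` and `p_value` (high p: no evidence against
#'   unimodality). Constant input returns p = 1 by convention.
#' @export
dip_test <- function(x, n_boot = 1000, seed = 1) {
  d <- dip_statistic(x)
  if (d == 0) return(list(dip = 0, p_value = 1))
  n <- sum(is.finite(x))
  old <- withr_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  null_d <- vapply(seq_len(n_boot),
                   function(i) dip_statistic(stats::runif(n)),
                   numeric(1))
  list(dip = d, p_value = (sum(null_d >= d) + 1) / (n_boot + 1))
}
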