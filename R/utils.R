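# Internal helpers shared across the pipeline.

# Time convention: frame index i (1-based in R) corresponds to time
# (i - 1) * dt_ms; intervals are half-open [t0, t1).

#' Central-difference time derivative of a 1-D signal
#'
#' The same estimator is used everywhere in the package (detection,
#' thresholding, repolarization fallback and test oracles): one frame on each
#' side, shrinking to a one-sided difference at the first and last sample.
#'
#' @param x numeric vector.
#' @param dt_ms sampling interval in ms.
#' @return numeric vector of `dF/dt` in signal units per ms.
#' @keywords internal
central_diff <- function(x, dt_ms = 1) {
  n <- length(x)
  if (n < 2L) return(rep(0, n))
  d <- numeric(n)
  d[2:(n - 1L)] <- (x[3:n] - x[1:(n - 2L)]) / (2 * dt_ms)
  d[1L] <- (x[2L] - x[1L]) / dt_ms
  d[n] <- (x[n] - x[n - 1L]) / dt_ms
  d
}

# Matrix version: x is T x P (time down the rows), returns same shape.
central_diff_mat <- function(x, dt_ms = 1) {
  n <- nrow(x)
  if (n < 2L) return(x * 0)
  d <- x * 0
  d[2:(n - 1L), ] <- (x[3:n, , drop = FALSE] - x[1:(n - 2L), , drop = FALSE]) / (2 * dt_ms)
  d[1L, ] <- (x[2L, ] - x[1L, ]) / dt_ms
  d[n, ] <- (x[n, ] - x[n - 1L, ]) / dt_ms
  d
}

# Least-squares slope of y against frame time (ms); NA-safe, two-point minimum.
ls_slope <- function(y, dt_ms = 1) {
  n <- length(y)
  if (n < 2L) return(NA_real_)
  t <- (seq_len(n) - 1) * dt_ms
  tc <- t - mean(t)
  sum(tc * (y - mean(y))) / sum(tc * tc)
}

# Convert a logical run-length mask to a two-column matrix of
# [start, end] 1-based inclusive frame indices of TRUE runs.
runs_to_intervals <- function(mask) {
  if (!any(mask)) return(matrix(integer(0), ncol = 2L))
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(starts[r$values], ends[r$values])
}

# Pixel linear index with x fastest (matches the raw-binary dialect and the
# scan order of the labeling scheme).
pixel_index <- function(x, y, nx) x + nx * (y - 1L)

`%||%` <- function(a, b) if (is.null(a)) b else a
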