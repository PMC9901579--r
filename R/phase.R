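# Pixel-independent action-potential upstroke windowing via Hilbert phase.

# FFT-based analytic signal of each column of a matrix (time down the rows).
analytic_signal_mat <- function(x) {
  n <- nrow(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1; h[n / 2 + 1L] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1L] <- 1; h[2:((n + 1L) / 2)] <- 2
  }
  stats::mvfft(stats::mvfft(x) * h, inverse = TRUE) / n
}

# 5% cosine (Tukey) taper to soften transform edge effects on short segments.
cosine_taper <- function(n, frac = 0.05) {
  w <- rep(1, n)
  m <- floor(frac * n)
  if (m >= 1L) {
    ramp <- 0.5 * (1 - cos(pi * seq_len(m) / (m + 1L)))
    w[seq_len(m)] <- ramp
    w[n + 1L - seq_len(m)] <- ramp
  }
  w
}

#' Instantaneous phase of a 1-D signal
#'
#' Hilbert-transform phase in \eqn{[0, 2\pi)}: the signal is mean-subtracted
#' internally, the quadrature component is formed by the Hilbert transform
#' (which imparts the \eqn{-90^\circ} phase shift to every spectral
#' component), and the phase is the angle of the analytic signal
#' \eqn{x + i H(x)}. Under this convention the rising edge of an action
#' potential falls in the \eqn{\varphi > \pi} half-cycle (see the methods
#' vignette for the worked sinusoid).
#'
#' @param signal numeric vector, length >= 4, non-constant.
#' @param taper_frac cosine-taper fraction applied before the transform.
#' @return numeric vector of phases in \eqn{[0, 2\pi)}.
#' @export
instantaneous_phase <- function(signal, taper_frac = 0) {
  n <- length(signal)
  if (n < 4L) stop("signal too short for phase computation (need >= 4 samples)")
  if (diff(range(signal)) == 0) stop("constant signal has no phase")
  x <- signal - mean(signal)
  if (taper_frac > 0) x <- x * cosine_taper(n, taper_frac)
  z <- analytic_signal_mat(matrix(x, ncol = 1L))[, 1L]
  Arg(z) %% (2 * pi)
}

# Segment boundaries of the recursive binary halving scheme: level 0 is the
# full trace; each level splits every segment in two; a level is skipped when
# halves would drop below min_len samples. Returns a matrix [start, end].
segment_tree <- function(n, min_len) {
  segs <- list(c(1L, n))
  out <- list(c(1L, n))
  repeat {
    nxt <- list()
    for (s in segs) {
      len <- s[2L] - s[1L] + 1L
      half1 <- len %/% 2L
      if (half1 >= min_len && (len - half1) >= min_len) {
        nxt[[length(nxt) + 1L]] <- c(s[1L], s[1L] + half1 - 1L)
        nxt[[length(nxt) + 1L]] <- c(s[1L] + half1, s[2L])
      }
    }
    if (!length(nxt)) break
    out <- c(out, nxt)
    segs <- nxt
  }
  do.call(rbind, out)
}

#' Phase-derived upstroke windows for a single pixel
#'
#' Computes \eqn{\varphi > \pi} windows from the Hilbert phase of the full
#' trace and of all recursive binary subdivisions down to segments of at least
#' `min_segment_ms`, and unions them. Recursive segmentation makes the phase
#' robust for non-periodic signals (isolated beats, transitions, pauses).
#' Unioned windows shorter than 3 samples are discarded (the derivative is
#' undefined there).
#'
#' @param signal numeric vector (one pixel's time series).
#' @param dt_ms frame interval in ms.
#' @param min_segment_ms minimum segment duration (default 128 ms).
#' @param taper_frac per-segment cosine taper fraction (default 0.05).
#' @return object of class `upstroke_windows`: list with `intervals` (two
#'   column matrix of 1-based inclusive start/end frames), `mask` (logical per
#'   frame), `dt_ms`.
#' @export
segmented_upstroke_windows <- function(signal, dt_ms = 1, min_segment_ms = 128,
                                       taper_frac = 0.05) {
  n <- length(signal)
  min_len <- max(4L, as.integer(round(min_segment_ms / dt_ms)))
  if (n < 4L) stop("signal too short (need >= 4 samples)")
  segs <- segment_tree(n, min(min_len, n))
  mask <- rep(FALSE, n)
  for (i in seq_len(nrow(segs))) {
    s <- segs[i, 1L]; e <- segs[i, 2L]
    x <- signal[s:e]
    if (diff(range(x)) == 0) next
    ph <- instantaneous_phase(x, taper_frac = taper_frac)
    mask[s:e] <- mask[s:e] | (ph > pi)
  }
  intervals <- runs_to_intervals(mask)
  keep <- (intervals[, 2L] - intervals[, 1L] + 1L) >= 3L
  intervals <- intervals[keep, , drop = FALSE]
  mask2 <- rep(FALSE, n)
  for (i in seq_len(nrow(intervals))) mask2[intervals[i, 1L]:intervals[i, 2L]] <- TRUE
  structure(list(intervals = intervals, mask = mask2, dt_ms = dt_ms,
                 min_segment_ms = min_segment_ms),
            class = "upstroke_windows")
}

#' Reject windows without a genuine rising deflection
#'
#' A retained window must have a positive in-window least-squares slope and an
#' in-window maximal first derivative of at least `deriv_threshold`
#' (normalized units per ms, central difference over one frame).
#'
#' @param signal the pixel's time series the windows were derived from.
#' @param windows an `upstroke_windows` object.
#' @param deriv_threshold minimum maximal derivative, >= 0; may also be a
#'   `derivative_threshold` object.
#' @return filtered `upstroke_windows` (possibly empty).
#' @export
filter_windows <- function(signal, windows, deriv_threshold = 0) {
  theta <- if (inherits(deriv_threshold, "derivative_threshold"))
    deriv_threshold$value else deriv_threshold
  if (theta < 0) stop("derivative threshold must be >= 0")
  iv <- windows$intervals
  if (!nrow(iv)) return(windows)
  d <- central_diff(signal, windows$dt_ms)
  keep <- logical(nrow(iv))
  for (i in seq_len(nrow(iv))) {
    s <- iv[i, 1L]; e <- iv[i, 2L]
    keep[i] <- ls_slope(signal[s:e], windows$dt_ms) > 0 &&
      max(d[s:e]) >= theta
  }
  out <- windows
  out$intervals <- iv[keep, , drop = FALSE]
  mask <- rep(FALSE, length(windows$mask))
  for (i in seq_len(nrow(out$intervals)))
    mask[out$intervals[i, 1L]:out$intervals[i, 2L]] <- TRUE
  out$mask <- mask
  out
}

#' Phase-derived upstroke windows for a whole stack
#'
#' Stack-level counterpart of [segmented_upstroke_windows()]: the same
#' segment boundaries apply to every pixel and the analytic signal is
#' batched across pixels (blocked to bound memory). Masked-out pixels get
#' empty interval sets.
#'
#' Windows are clipped to an edge guard band of `guard_ms` at both record
#' boundaries: the first and last few tens of ms cannot hold a resolvable
#' complete upstroke, because the per-pixel min-max normalization anchors
#' the trace minimum there and the zero-phase filters have their warm-up,
#' which together produce slow spurious rises.
#'
#' @param stack a preconditioned [voltage_stack()].
#' @param min_segment_ms minimum phase-segment duration (default 128 ms).
#' @param taper_frac per-segment cosine taper fraction.
#' @param guard_ms edge guard band in ms (0 disables).
#' @param block pixels per FFT batch.
#' @return object of class `stack_windows`: list with `intervals_by_pixel`
#'   (one start/end matrix per pixel, x fastest), `dims`, `dt_ms`.
#' @export
stack_upstroke_windows <- function(stack, min_segment_ms = 128,
                                   taper_frac = 0.05, guard_ms = 25,
                                   block = 512L) {
  d <- dim(stack$data); nx <- d[1L]; ny <- d[2L]; nt <- d[3L]
  guard <- as.integer(round(guard_ms / stack$dt_ms))
  lo <- guard + 1L; hi <- nt - guard
  if (hi - lo < 3L) stop("recording shorter than twice the edge guard")
  min_len <- max(4L, as.integer(round(min_segment_ms / stack$dt_ms)))
  segs <- segment_tree(nt, min(min_len, nt))
  m <- stack_as_matrix(stack)
  in_idx <- which(as.vector(stack$mask))
  res <- vector("list", nx * ny)
  for (blk in split(in_idx, ceiling(seq_along(in_idx) / block))) {
    xb <- m[, blk, drop = FALSE]
    mask_b <- matrix(FALSE, nt, length(blk))
    for (i in seq_len(nrow(segs))) {
      s <- segs[i, 1L]; e <- segs[i, 2L]
      seg <- xb[s:e, , drop = FALSE]
      mu <- colMeans(seg)
      live <- colMeans(seg * seg) - mu * mu > 0    # non-constant columns
      if (!any(live)) next
      segl <- sweep(seg[, live, drop = FALSE], 2L, mu[live])
      if (taper_frac > 0) segl <- segl * cosine_taper(e - s + 1L, taper_frac)
      z <- analytic_signal_mat(segl)
      ph <- Arg(z) %% (2 * pi)
      mask_b[s:e, live] <- mask_b[s:e, live, drop = FALSE] | (ph > pi)
    }
    for (j in seq_along(blk)) {
      iv <- runs_to_intervals(mask_b[, j])
      if (nrow(iv)) {                       # clip to the edge guard band
        iv[, 1L] <- pmax(iv[, 1L], lo)
        iv[, 2L] <- pmin(iv[, 2L], hi)
      }
      iv <- iv[(iv[, 2L] - iv[, 1L] + 1L) >= 3L, , drop = FALSE]
      res[[blk[j]]] <- iv
    }
  }
  empty <- matrix(integer(0), ncol = 2L)
  for (k in seq_len(nx * ny)) if (is.null(res[[k]])) res[[k]] <- empty
  structure(list(intervals_by_pixel = res, dims = d, dt_ms = stack$dt_ms,
                 min_segment_ms = min_segment_ms),
            class = "stack_windows")
}

#' Export upstroke windows as a per-pixel interval list (CSV)
#'
#' Columns: `x`, `y`, `t_start_ms`, `t_end_ms` (closed intervals).
#' @param windows a `stack_windows` object.
#' @param path output path.
#' @export
write_windows_csv <- function(windows, path) {
  nx <- windows$dims[1L]
  rows <- lapply(seq_along(windows$intervals_by_pixel), function(px) {
    iv <- windows$intervals_by_pixel[[px]]
    if (!nrow(iv)) return(NULL)
    data.table::data.table(
      x = ((px - 1L) %% nx) + 1L, y = ((px - 1L) %/% nx) + 1L,
      t_start_ms = (iv[, 1L] - 1L) * windows$dt_ms,
      t_end_ms = (iv[, 2L] - 1L) * windows$dt_ms)
  })
  out <- data.table::rbindlist(rows[!vapply(rows, is.null, logical(1L))])
  data.table::fwrite(out, path)
  invisible(path)
}
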