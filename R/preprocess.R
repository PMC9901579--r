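#' Pre-condition a raw optical-mapping stack
#'
#' Standard conditioning of voltage-sensitive fluorescence movies before
#' activation analysis: a forwards-backwards (zero-phase) Butterworth low-pass
#' along time, a spatial uniform average, a uniform running-average temporal
#' filter, then per-pixel inversion (fluorescence falls on depolarization) and
#' min-max normalization to \eqn{[0, 1]}. Defaults are a 60 Hz cutoff with
#' 3 x 3 pixel and 3-frame kernels.
#'
#' The spatial kernel is mask-aware and shrinks at borders: each pixel is the
#' average of the available masked-in neighbors, so mask boundaries do not
#' bleed background zeros into tissue. Pixels whose signal has zero range
#' normalize to 0 (the 0/0 degenerate case is defined as 0).
#'
#' @param raw a [voltage_stack()] or a numeric `(nx, ny, nt)` array.
#' @param cutoff_hz low-pass cutoff in Hz (must be below Nyquist).
#' @param spatial_kernel odd spatial kernel edge in pixels.
#' @param temporal_kernel odd temporal kernel in frames.
#' @param mask optional logical ROI matrix; if supplied it is also applied
#'   (masked-out pixels zeroed) as in [apply_roi_mask()].
#' @param dt_ms,pitch_mm used only when `raw` is a bare array.
#' @param order Butterworth order (3 by default).
#' @return a normalized [voltage_stack()].
#' @export
precondition_stack <- function(raw, cutoff_hz = 60, spatial_kernel = 3L,
                               temporal_kernel = 3L, mask = NULL,
                               dt_ms = 1, pitch_mm = 0.7, order = 3L) {
  if (!inherits(raw, "voltage_stack"))
    raw <- voltage_stack(raw, dt_ms = dt_ms, pitch_mm = pitch_mm)
  d <- dim(raw$data); nx <- d[1L]; ny <- d[2L]; nt <- d[3L]
  if (spatial_kernel %% 2L == 0L || temporal_kernel %% 2L == 0L)
    stop("kernels must be odd")
  if (nx < 2L * spatial_kernel || ny < 2L * spatial_kernel)
    stop("stack too small for the spatial kernel")
  if (nt < temporal_kernel) stop("stack shorter than the temporal kernel")
  fs <- 1000 / raw$dt_ms
  if (cutoff_hz >= fs / 2)
    stop("cutoff must be below the Nyquist frequency (", fs / 2, " Hz)")
  if (!is.null(mask)) {
    mask <- matrix(as.logical(mask), nx, ny)
    if (!any(mask)) stop("empty ROI mask")
  } else {
    mask <- raw$mask
  }

  bw <- butter_lowpass(order, cutoff_hz, fs)
  m <- stack_as_matrix(raw)
  m <- filtfilt_mat(bw$b, bw$a, m)
  arr <- matrix_as_stack_data(m, nx, ny)
  arr <- spatial_uniform_filter(arr, spatial_kernel, mask)
  m <- aperm(arr, c(3L, 1L, 2L)); dim(m) <- c(nt, nx * ny)
  m <- .running_mean_mat(m, as.integer(temporal_kernel))

  # invert and per-pixel min-max normalize; zero-range pixels map to 0
  # (range below numerical noise of the filters counts as zero)
  mx <- apply(m, 2L, max); mn <- apply(m, 2L, min)
  rng <- mx - mn
  tol <- 1e-9 * pmax(1, abs(mx), abs(mn))
  scale <- ifelse(rng > tol, 1 / rng, 0)
  m <- sweep(sweep(-m, 2L, -mx, "-"), 2L, scale, "*") # (max - F) / range
  m[, !as.vector(mask)] <- 0

  voltage_stack(matrix_as_stack_data(m, nx, ny), dt_ms = raw$dt_ms,
                pitch_mm = raw$pitch_mm, mask = mask,
                meta = c(raw$meta,
                         list(preconditioned = TRUE, cutoff_hz = cutoff_hz,
                              order = order, spatial_kernel = spatial_kernel,
                              temporal_kernel = temporal_kernel)))
}

# Mask-aware uniform spatial average of a (nx, ny, nt) array; the kernel
# shrinks at image borders and at mask boundaries (only masked-in neighbors
# contribute). Masked-out pixels are passed through untouched.
spatial_uniform_filter <- function(arr, k, mask) {
  d <- dim(arr); nx <- d[1L]; ny <- d[2L]
  h <- (k - 1L) %/% 2L
  acc <- array(0, d)
  cnt <- matrix(0, nx, ny)
  w <- mask * 1
  for (dx in -h:h) {
    xs <- max(1L, 1L - dx):min(nx, nx - dx)   # destination x range
    xn <- xs + dx                             # source (neighbor) x range
    for (dy in -h:h) {
      ys <- max(1L, 1L - dy):min(ny, ny - dy)
      yn <- ys + dy
      wsub <- w[xn, yn, drop = FALSE]
      acc[xs, ys, ] <- acc[xs, ys, , drop = FALSE] +
        sweep(arr[xn, yn, , drop = FALSE], c(1L, 2L), wsub, "*")
      cnt[xs, ys] <- cnt[xs, ys] + wsub
    }
  }
  cnt[cnt == 0] <- 1
  out <- sweep(acc, c(1L, 2L), cnt, "/")
  out[!mask] <- arr[!mask]                    # leave background untouched here
  out
}

#' Apply a region-of-interest mask to a stack
#'
#' Masked-out pixel series are set identically to zero; masked-in series are
#' unchanged. Masked-out pixels then propagate as exact zeros through the
#' whole downstream pipeline (no windows, no events, sentinels in maps).
#'
#' @param stack a [voltage_stack()].
#' @param mask logical matrix matching the stack's spatial shape.
#' @return the masked [voltage_stack()].
#' @export
apply_roi_mask <- function(stack, mask) {
  d <- dim(stack$data)
  mask <- matrix(as.logical(mask), nrow = d[1L])
  if (!identical(dim(mask), d[1:2])) stop("mask shape does not match stack")
  if (!any(mask)) stop("empty ROI mask (all pixels excluded)")
  out <- stack
  idx <- which(!mask)
  if (length(idx)) {
    m <- stack_as_matrix(stack)
    m[, idx] <- 0
    out$data <- matrix_as_stack_data(m, d[1L], d[2L])
  }
  out$mask <- mask
  out
}

#' Per-pixel signal-quality metrics
#'
#' Computes, for every masked-in pixel: the signal-to-noise ratio, the
#' dominant frequency of the spectrum, and a regularity index. The paper-style
#' quantities are reported under explicit definitions (recorded in the result):
#' \itemize{
#'   \item SNR: peak-to-peak of the low-passed signal (cutoff = lower edge of
#'     `noise_band_hz`) divided by the standard deviation of the residual
#'     above that edge.
#'   \item dominant frequency: spectral peak over frequencies >= `f_min_hz`.
#'   \item regularity index: fraction of (non-DC) spectral power within
#'     +/- 0.75 Hz of the dominant peak, a common fibrillation-analysis
#'     convention.
#' }
#' Constant (e.g. masked-out or dead) pixels are flagged undefined (`NA`),
#' not 0.
#'
#' @param stack a (preconditioned) [voltage_stack()].
#' @param noise_band_hz numeric: lower edge of the noise band in Hz (default 60).
#' @param f_min_hz minimum frequency searched for the dominant peak.
#' @param band_hz half-width of the regularity band in Hz.
#' @return object of class `signal_qc`: list of three [scalar_map()]s (`snr`,
#'   `dominant_freq_hz`, `regularity_index`) plus the definitions used.
#' @export
signal_qc <- function(stack, noise_band_hz = 60, f_min_hz = 0.5,
                      band_hz = 0.75) {
  d <- dim(stack$data); nx <- d[1L]; ny <- d[2L]; nt <- d[3L]
  fs <- 1000 / stack$dt_ms
  if (nt * stack$dt_ms < 1000)
    stop("stack duration must be >= 1 s for spectral estimates")
  m <- stack_as_matrix(stack)
  in_idx <- which(as.vector(stack$mask))

  bw <- butter_lowpass(3L, noise_band_hz, fs)
  lp <- filtfilt_mat(bw$b, bw$a, m[, in_idx, drop = FALSE])
  resid <- m[, in_idx, drop = FALSE] - lp
  p2p <- apply(lp, 2L, function(v) diff(range(v)))
  nsd <- apply(resid, 2L, stats::sd)
  snr_v <- ifelse(p2p > 0 & nsd > 0, p2p / nsd, NA_real_)

  # one-sided periodogram of mean-subtracted signals
  xm <- sweep(m[, in_idx, drop = FALSE], 2L, colMeans(m[, in_idx, drop = FALSE]))
  sp <- Mod(stats::mvfft(xm))^2
  nf <- floor(nt / 2)
  freqs <- (seq_len(nf)) * fs / nt          # positive frequencies, no DC
  sp <- sp[1L + seq_len(nf), , drop = FALSE]
  searchable <- freqs >= f_min_hz
  dom_v <- reg_v <- rep(NA_real_, length(in_idx))
  tot <- colSums(sp)
  ok <- tot > 0
  if (any(searchable) && any(ok)) {
    pk <- apply(sp[searchable, ok, drop = FALSE], 2L, which.max)
    fpk <- freqs[searchable][pk]
    dom_v[ok] <- fpk
    for (j in seq_along(which(ok))) {
      jj <- which(ok)[j]
      band <- abs(freqs - fpk[j]) <= band_hz
      reg_v[jj] <- sum(sp[band, jj]) / tot[jj]
    }
  }

  mk <- function(vals, units) {
    mat <- matrix(NA_real_, nx, ny)
    mat[in_idx] <- vals
    scalar_map(mat, units = units, pitch_mm = stack$pitch_mm)
  }
  structure(list(snr = mk(snr_v, "ratio"),
                 dominant_freq_hz = mk(dom_v, "Hz"),
                 regularity_index = mk(reg_v, "fraction"),
                 definitions = list(
                   snr = sprintf("p2p(lowpass %g Hz) / sd(residual above %g Hz)",
                                 noise_band_hz, noise_band_hz),
                   dominant_freq = sprintf("spectral argmax over f >= %g Hz", f_min_hz),
                   regularity = sprintf("power fraction within +/- %g Hz of peak", band_hz))),
            class = "signal_qc")
}

#' @export
print.signal_qc <- function(x, ...) {
  cat("<signal_qc>\n")
  for (nm in c("snr", "dominant_freq_hz", "regularity_index")) {
    v <- x[[nm]]
    cat(sprintf("  %-18s median %.3g (n = %d defined)\n", nm,
                stats::median(v, na.rm = TRUE), sum(!is.na(v))))
  }
  invisible(x)
}
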