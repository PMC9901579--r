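# Digital Butterworth design and zero-phase filtering.
#
# No signal-processing package is assumed: the low-pass design (bilinear
# transform of the analog prototype) and forwards-backwards filtering with
# odd-reflection padding and steady-state initial conditions are implemented
# here and validated in tests against the analytic squared magnitude
# |H(f)|^2 = 1 / (1 + (f/fc)^(2n)).

# polynomial coefficients (descending powers) from roots
poly_from_roots <- function(r) {
  coef <- 1 + 0i
  for (ri in r) coef <- c(coef, 0) - ri * c(0, coef)
  coef
}

#' Digital Butterworth low-pass filter coefficients
#'
#' @param n filter order (the pipeline uses 3).
#' @param fc cutoff frequency in Hz.
#' @param fs sampling frequency in Hz; `fc` must be below `fs / 2`.
#' @return list with numerator `b` and denominator `a` (a\[1\] = 1).
#' @export
butter_lowpass <- function(n, fc, fs) {
  if (fc >= fs / 2) stop("cutoff must be below the Nyquist frequency (", fs / 2, " Hz)")
  if (fc <= 0 || n < 1) stop("invalid Butterworth design parameters")
  Wn <- fc / (fs / 2)
  warped <- 4 * tan(pi * Wn / 2)           # prewarped analog cutoff (fs = 2)
  k <- seq_len(n)
  p <- warped * exp(1i * pi * (2 * k + n - 1) / (2 * n))  # left-half-plane poles
  gain <- warped^n
  fs2 <- 4                                  # 2 * fs with fs = 2
  zp <- (fs2 + p) / (fs2 - p)               # bilinear transform
  gain_z <- Re(gain / prod(fs2 - p))
  b <- Re(poly_from_roots(rep(-1 + 0i, n))) * gain_z
  a <- Re(poly_from_roots(zp))
  list(b = b, a = a / a[1L])
}

# steady-state initial filter state for a unit step (scipy lfilter_zi)
lfilter_zi <- function(b, a) {
  n <- max(length(a), length(b))
  b <- c(b, rep(0, n - length(b)))
  a <- c(a, rep(0, n - length(a)))
  if (n == 1L) return(numeric(0))
  # companion matrix of a, transposed
  A <- matrix(0, n - 1L, n - 1L)
  A[1L, ] <- -a[-1L] / a[1L]
  if (n > 2L) A[cbind(2:(n - 1L), 1:(n - 2L))] <- 1
  IminusA <- diag(n - 1L) - t(A)
  B <- b[-1L] - a[-1L] * b[1L]
  solve(IminusA, B)
}

#' Zero-phase (forwards-backwards) filtering of a multichannel matrix
#'
#' Applies the IIR filter forwards then backwards down the rows of `x`
#' (time along rows, one signal per column), with odd-reflection padding and
#' steady-state initial conditions so that no group delay or edge transient is
#' introduced. The magnitude response applied is the squared single-pass
#' magnitude.
#'
#' @param b,a filter coefficients from [butter_lowpass()].
#' @param x numeric matrix (time x signals) or vector.
#' @return filtered data with the same shape as `x`.
#' @export
filtfilt_mat <- function(b, a, x) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, ncol = 1L)
  nt <- nrow(x)
  padlen <- 3L * (max(length(a), length(b)) - 1L)
  if (nt <= padlen + 1L)
    stop("stack shorter than filter warm-up (need > ", padlen + 1L, " frames)")
  zi <- lfilter_zi(b, a)
  ext <- rbind(2 * x[rep(1L, padlen), , drop = FALSE] - x[(padlen + 1L):2, , drop = FALSE],
               x,
               2 * x[rep(nt, padlen), , drop = FALSE] - x[(nt - 1L):(nt - padlen), , drop = FALSE])
  y <- .df2t_filter_mat(b, a, ext, zi, ext[1L, ])
  y <- y[nrow(y):1L, , drop = FALSE]
  y <- .df2t_filter_mat(b, a, y, zi, y[1L, ])
  y <- y[nrow(y):1L, , drop = FALSE]
  y <- y[(padlen + 1L):(padlen + nt), , drop = FALSE]
  if (vec) y <- y[, 1L]
  y
}
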