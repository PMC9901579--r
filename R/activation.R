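# Activation-time detection inside phase-derived upstroke windows.

#' Automated signal-derivative threshold via false-discovery-rate control
#'
#' Optical-signal derivatives are noise-sensitive, so a minimum maximal
#' derivative \eqn{\theta_{dF/dt} > 0} is required for a window to count as a
#' depolarizing event. The automated procedure treats each window's maximal
#' derivative as a test statistic against a per-pixel noise null (the robust
#' MAD scale of the pixel's full derivative trace). For a cutoff `c` the
#' expected number of noise windows at or above `c` is the sum over all
#' windows of `P(max of L null derivatives >= c)` under their own nulls; the
#' estimated FDR at `c` is that expectation divided by the observed count at
#' or above `c`. The threshold is the smallest cutoff whose retained set has
#' estimated FDR at most `fdr_q` - the value at which the retained windows
#' carry the maximum desired false discovery rate. On pure-noise stacks the
#' expected pass fraction is below `fdr_q` (there the estimator is
#' conservative); on clean stacks the threshold falls below the weakest true
#' upstroke. If no cutoff achieves the target, the threshold is placed above
#' every observed value (nothing passes).
#'
#' @param stack a preconditioned [voltage_stack()].
#' @param windows a `stack_windows` object from [stack_upstroke_windows()].
#' @param fdr_q target false discovery rate (default 0.01, i.e. 1%).
#' @return object of class `derivative_threshold` with fields `value`,
#'   `method`, `fdr_q`, `n_windows`, `n_significant`.
#' @export
auto_derivative_threshold <- function(stack, windows, fdr_q = 0.01) {
  if (fdr_q <= 0 || fdr_q >= 1) stop("fdr_q must be in (0, 1)")
  d <- dim(stack$data)
  m <- stack_as_matrix(stack)
  acc <- list(); na <- 0L
  for (px in which(as.vector(stack$mask))) {
    iv <- windows$intervals_by_pixel[[px]]
    if (!nrow(iv)) next
    dd <- central_diff(m[, px], stack$dt_ms)
    # noise scale of the derivative trace; floored at 1% of the pixel's peak
    # derivative so that noiseless records (MAD ~ 0) do not declare every
    # numerical micro-fluctuation significant
    sigma <- max(stats::mad(dd), 0.01 * max(dd, 0), .Machine$double.xmin)
    L <- iv[, 2L] - iv[, 1L] + 1L
    v <- vapply(seq_len(nrow(iv)), function(i)
      max(dd[iv[i, 1L]:iv[i, 2L]]), numeric(1L))
    na <- na + 1L
    acc[[na]] <- cbind(v, sigma, L)
  }
  wtab <- if (na) do.call(rbind, acc) else matrix(numeric(0), ncol = 3L)
  vals <- wtab[, 1L]; sigmas <- wtab[, 2L]; lens <- wtab[, 3L]
  nw <- length(vals)
  if (nw < 50L)
    stop("only ", nw, " windows available (need >= 50); ",
         "set a manual derivative threshold instead")
  # expected number of noise windows with max derivative >= c under the
  # per-window extreme-value nulls (numerically stable in the tail)
  expected_noise <- function(c) {
    lp <- stats::pnorm(c, mean = 0, sd = sigmas, log.p = TRUE)
    sum(-expm1(lens * lp))
  }
  fdr_at <- function(c) {
    n_obs <- sum(vals >= c)
    if (n_obs == 0L) return(0)
    min(1, expected_noise(c) / n_obs)
  }
  hi <- max(vals)
  if (fdr_at(hi) > fdr_q) {
    value <- hi * (1 + 1e-9) + .Machine$double.eps   # nothing passes
    nsig <- 0L
  } else {
    # smallest cutoff with estimated FDR <= q (bisection; fdr_at is
    # monotone-decreasing up to discreteness of the observed counts)
    lo <- 0
    for (it in 1:60) {
      mid <- (lo + hi) / 2
      if (fdr_at(mid) <= fdr_q) hi <- mid else lo <- mid
    }
    keep <- vals >= hi
    value <- max(min(vals[keep]), .Machine$double.eps)
    nsig <- sum(keep)
  }
  structure(list(value = value, method = "auto", fdr_q = fdr_q,
                 n_windows = nw, n_significant = nsig),
            class = "derivative_threshold")
}

#' Manually specified derivative threshold
#' @param value threshold in normalized units per ms, > 0.
#' @return a `derivative_threshold` object.
#' @export
manual_derivative_threshold <- function(value) {
  if (value <= 0) stop("derivative threshold must be > 0")
  structure(list(value = value, method = "manual", fdr_q = NA_real_),
            class = "derivative_threshold")
}

#' @export
print.derivative_threshold <- function(x, ...) {
  cat(sprintf("<derivative_threshold> %.4g /ms (%s%s)\n", x$value, x$method,
              if (x$method == "auto")
                sprintf(", q = %g, %d/%d windows significant", x$fdr_q,
                        x$n_significant, x$n_windows) else ""))
  invisible(x)
}

#' Detect one or two activation times inside an upstroke window
#'
#' Optical upstrokes integrate several tissue layers and can be biphasic:
#' two local maxima of the signal derivative may mark two distinct
#' depolarization events. If the two largest in-window derivative maxima both
#' exceed the threshold and the derivative valley between them is deep enough
#' (depth relative to the smaller maximum at least `valley_frac`, default
#' 75%), two activation times are returned - the chronologically first is the
#' primary component. Otherwise a single activation is returned at the global
#' in-window derivative maximum (earliest sample on ties). Each event carries
#' \eqn{V_F^*}, the maximal derivative normalized by the in-window signal
#' amplitude.
#'
#' @param signal the pixel's full time series.
#' @param window integer vector `c(start, end)` (1-based inclusive frames).
#' @param threshold a `derivative_threshold` or a bare number.
#' @param valley_frac minimum relative valley depth for a split (default 0.75).
#' @param dt_ms frame interval in ms.
#' @return data.frame with columns `t_frame`, `t_ms`, `component`
#'   (`"primary"`/`"secondary"`), `vf_star`.
#' @export
detect_upstroke_activations <- function(signal, window, threshold,
                                        valley_frac = 0.75, dt_ms = 1) {
  theta <- if (inherits(threshold, "derivative_threshold"))
    threshold$value else threshold
  s <- window[1L]; e <- window[2L]
  if (e - s + 1L < 3L) stop("window shorter than 3 samples")
  d <- central_diff(signal, dt_ms)[s:e]
  amp <- diff(range(signal[s:e]))
  if (amp <= 0) return(activation_df())
  # plateau-aware local maxima: a run of equal derivative values is one
  # candidate peak at its earliest sample (ties break to earliest time)
  r <- rle(d)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  vl <- c(-Inf, r$values[-length(r$values)])
  vr <- c(r$values[-1L], -Inf)
  peaks <- starts[r$values > vl & r$values > vr]
  peaks <- peaks[d[peaks] >= theta]
  if (!length(peaks)) {
    gm <- which.max(d)
    if (d[gm] < theta) return(activation_df())
    peaks <- gm
  }
  if (length(peaks) >= 2L) {
    top2 <- peaks[order(-d[peaks], peaks)][1:2]
    top2 <- sort(top2)
    smaller <- min(d[top2[1L]], d[top2[2L]])
    valley <- min(d[top2[1L]:top2[2L]])
    depth <- if (smaller > 0) (smaller - valley) / smaller else -Inf
    if (depth >= valley_frac) {
      return(activation_df(
        t_frame = s - 1L + top2,
        t_ms = (s - 2L + top2) * dt_ms,
        component = c("primary", "secondary"),
        vf_star = d[top2] * dt_ms / amp))
    }
  }
  gm <- peaks[which.max(d[peaks])]
  activation_df(t_frame = s - 1L + gm, t_ms = (s - 2L + gm) * dt_ms,
                component = "primary", vf_star = d[gm] * dt_ms / amp)
}

activation_df <- function(t_frame = integer(0), t_ms = numeric(0),
                          component = character(0), vf_star = numeric(0)) {
  data.frame(t_frame = as.integer(t_frame), t_ms = t_ms,
             component = component, vf_star = vf_star)
}

#' Build the activation matrix (pAT events) for a whole stack
#'
#' Applies window filtering ([filter_windows()]) and
#' [detect_upstroke_activations()] to every masked-in pixel and retained
#' window. Events are sorted by `(t, y, x)` - the scan order used by the
#' wave-front labeling stage.
#'
#' @param stack a preconditioned [voltage_stack()].
#' @param windows a `stack_windows` object.
#' @param threshold a `derivative_threshold`.
#' @param valley_frac biphasic split threshold (default 0.75).
#' @return object of class `activation_events`: a [data.table::data.table]
#'   with columns `x`, `y`, `t_frame`, `t_ms`, `component`, `vf_star`,
#'   `window_id`, `pixel`, plus attributes `dims`, `dt_ms`.
#' @export
build_activation_matrix <- function(stack, windows, threshold,
                                    valley_frac = 0.75) {
  d <- dim(stack$data); nx <- d[1L]; ny <- d[2L]
  theta <- if (inherits(threshold, "derivative_threshold"))
    threshold$value else threshold
  m <- stack_as_matrix(stack)
  # window table in scan order over masked-in pixels; the row number is the
  # global window id
  in_px <- which(as.vector(stack$mask))
  nwin <- vapply(windows$intervals_by_pixel[in_px], nrow, integer(1L))
  win <- cbind(rep(in_px, nwin),
               do.call(rbind, windows$intervals_by_pixel[in_px]))
  storage.mode(win) <- "integer"
  ev <- if (length(win) && nrow(win)) {
    hits <- .detect_events_batch(m, win, theta, valley_frac, stack$dt_ms)
    if (nrow(hits)) {
      px <- win[hits[, "window_row"], 1L]
      data.table::data.table(
        x = ((px - 1L) %% nx) + 1L,
        y = ((px - 1L) %/% nx) + 1L,
        t_frame = as.integer(hits[, "frame"]),
        t_ms = (hits[, "frame"] - 1) * stack$dt_ms,
        component = c("primary", "secondary")[hits[, "component"]],
        vf_star = hits[, "vf_star"],
        window_id = as.integer(hits[, "window_row"]),
        pixel = px)
    } else NULL
  } else NULL
  if (is.null(ev))
    ev <- data.table::as.data.table(
      cbind(activation_df(), data.frame(x = integer(0), y = integer(0),
                                        window_id = integer(0),
                                        pixel = integer(0))))
  data.table::setcolorder(ev, c("x", "y", "t_frame", "t_ms", "component",
                                "vf_star", "window_id", "pixel"))
  data.table::setorder(ev, t_frame, y, x)
  data.table::setattr(ev, "dims", d)
  data.table::setattr(ev, "dt_ms", stack$dt_ms)
  data.table::setattr(ev, "pitch_mm", stack$pitch_mm)
  data.table::setattr(ev, "class", c("activation_events", class(ev)))
  ev
}

#' @export
print.activation_events <- function(x, ...) {
  cat(sprintf("<activation_events> %d events (%d secondary) on %d pixels\n",
              nrow(x), sum(x$component == "secondary"),
              length(unique(x$pixel))))
  if (nrow(x)) NextMethod()
  invisible(x)
}

#' Export activation events as CSV
#' @param events an `activation_events` table.
#' @param path output path.
#' @export
write_events_csv <- function(events, path) {
  data.table::fwrite(events[, c("x", "y", "t_ms", "component", "vf_star")],
                     path)
  invisible(path)
}

#' Densify activation events into a boolean stack
#'
#' The activation matrix as a dense `(nx, ny, nt)` stack with 1 at every
#' event's `(x, y, t)` and 0 elsewhere; serializable with
#' [write_raw_stack()] (`dtype = "uint16"`).
#'
#' @param events an `activation_events` table.
#' @return a [voltage_stack()] holding the indicator stack.
#' @export
events_to_stack <- function(events) {
  d <- attr(events, "dims")
  arr <- array(0, dim = d)
  if (nrow(events)) arr[cbind(events$x, events$y, events$t_frame)] <- 1
  voltage_stack(arr, dt_ms = attr(events, "dt_ms") %||% 1,
                pitch_mm = attr(events, "pitch_mm") %||% 0.7,
                meta = list(kind = "activation_matrix"))
}

#' Uniform-window activation map (baseline method)
#'
#' The classical baseline: one fixed time window common to all pixels; each
#' pixel's activation time is the time of its maximal derivative inside
#' `[t0_ms, t1_ms)`. Kept for comparison with the phase-windowed method - on
#' reentrant records a uniform window straddles cycles and produces
#' discontinuous maps.
#'
#' @param stack a preconditioned [voltage_stack()].
#' @param t0_ms,t1_ms half-open window in ms within the recording.
#' @param threshold optional `derivative_threshold`; pixels whose in-window
#'   maximal derivative is below it are left unassigned.
#' @return a [scalar_map()] of activation times in ms.
#' @export
uniform_window_at <- function(stack, t0_ms, t1_ms, threshold = NULL) {
  d <- dim(stack$data); nt <- d[3L]
  s <- as.integer(floor(t0_ms / stack$dt_ms)) + 1L
  e <- as.integer(ceiling(t1_ms / stack$dt_ms))      # [t0, t1) in frames
  if (t0_ms >= t1_ms || s > nt || e < 1L) stop("empty uniform window")
  s <- max(1L, s); e <- min(nt, e)
  if (e - s + 1L < 2L) stop("uniform window too short")
  theta <- if (is.null(threshold)) -Inf else
    if (inherits(threshold, "derivative_threshold")) threshold$value else threshold
  m <- stack_as_matrix(stack)
  dd <- central_diff_mat(m[s:e, , drop = FALSE], stack$dt_ms)
  at <- rep(NA_real_, ncol(m))
  for (px in which(as.vector(stack$mask))) {
    i <- which.max(dd[, px])
    if (dd[i, px] >= theta) at[px] <- (s - 2L + i) * stack$dt_ms
  }
  scalar_map(matrix(at, d[1L], d[2L]), units = "ms", pitch_mm = stack$pitch_mm)
}
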