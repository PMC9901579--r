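# Repolarization-time and action-potential-duration mapping per wave front.

#' Repolarization mapping configuration
#'
#' @param level_frac fractional amplitude drop from the action-potential peak
#'   defining repolarization (default 0.8, i.e. APD80).
#' @param apd_min_ms,apd_max_ms user APD search limits in ms (defaults
#'   80-400 ms, suitable for ventricular myocardium at physiological rates).
#' @param method `"amplitude_crossing"` (default) or `"min_derivative"`; the
#'   derivative method is the fallback for drifting baselines, taking the
#'   time of steepest signal fall instead of a fixed amplitude level.
#' @return a `repolarization_config` object.
#' @export
repolarization_config <- function(level_frac = 0.8, apd_min_ms = 80,
                                  apd_max_ms = 400,
                                  method = c("amplitude_crossing",
                                             "min_derivative")) {
  if (level_frac <= 0 || level_frac >= 1) stop("level_frac must be in (0, 1)")
  if (apd_min_ms <= 0 || apd_min_ms >= apd_max_ms)
    stop("need 0 < apd_min_ms < apd_max_ms")
  structure(list(level_frac = level_frac, apd_min_ms = apd_min_ms,
                 apd_max_ms = apd_max_ms, method = match.arg(method)),
            class = "repolarization_config")
}

#' Refine APD limits from a wave front's own resolved durations
#'
#' Per-front second-pass limits: the 5th and 95th percentiles of the APDs
#' already resolved within the front, widened by 10 ms on each side and
#' clipped to the user limits. With no resolvable duration the user limits
#' are returned with a warning.
#'
#' @param apds_ms numeric vector of first-pass APDs (NAs ignored).
#' @param config a [repolarization_config()].
#' @return numeric `c(apd_min, apd_max)` in ms.
#' @export
refine_apd_limits <- function(apds_ms, config) {
  apds_ms <- apds_ms[is.finite(apds_ms)]
  if (!length(apds_ms))
    warning("no resolvable repolarization in front; using user APD limits")
  if (length(apds_ms) < 2L)   # percentiles need at least two durations
    return(c(config$apd_min_ms, config$apd_max_ms))
  q <- stats::quantile(apds_ms, c(0.05, 0.95), names = FALSE)
  c(max(config$apd_min_ms, q[1L] - 10), min(config$apd_max_ms, q[2L] + 10))
}

#' Repolarization time of one action potential
#'
#' Searches `[pat + apd_min, pat + apd_max]`. The amplitude method takes the
#' first downward crossing of `peak - level_frac * amplitude` after the peak,
#' where the peak is the signal maximum in `[pat, pat + apd_max]` and the
#' amplitude is peak minus the pre-upstroke baseline (median of the 10 ms
#' before `pat`). The derivative method takes the time of the minimum signal
#' derivative in the search interval and is robust to baseline drift.
#'
#' @param signal the pixel's time series.
#' @param pat_ms activation time in ms.
#' @param config a [repolarization_config()].
#' @param limits optional refined `c(min, max)` APD limits in ms.
#' @param dt_ms frame interval in ms.
#' @return repolarization time in ms, or `NA` if no crossing exists in the
#'   interval (pixel then excluded from the APD map).
#' @export
detect_repolarization <- function(signal, pat_ms, config, limits = NULL,
                                  dt_ms = 1) {
  lim <- limits %||% c(config$apd_min_ms, config$apd_max_ms)
  nt <- length(signal)
  ip <- as.integer(round(pat_ms / dt_ms)) + 1L        # frame of pAT
  if (ip + lim[1L] / dt_ms > nt) return(NA_real_)
  i0 <- min(nt, ip + as.integer(floor(lim[1L] / dt_ms)))
  i1 <- min(nt, ip + as.integer(ceiling(lim[2L] / dt_ms)))
  if (config$method == "min_derivative") {
    d <- central_diff(signal, dt_ms)
    k <- i0 - 1L + which.min(d[i0:i1])
    return((k - 1L) * dt_ms)
  }
  ipk <- ip - 1L + which.max(signal[ip:i1])            # AP peak
  peak <- signal[ipk]
  b0 <- max(1L, ip - as.integer(round(10 / dt_ms)))
  base <- if (b0 < ip) stats::median(signal[b0:(ip - 1L)]) else signal[ip]
  amp <- peak - base
  if (amp <= 0) return(NA_real_)
  level <- peak - config$level_frac * amp
  lo <- max(i0, ipk + 1L)
  if (lo > i1) return(NA_real_)
  below <- signal[lo:i1] < level
  above_prev <- signal[(lo - 1L):(i1 - 1L)] >= level
  k <- which(below & above_prev)
  if (!length(k)) return(NA_real_)
  (lo + k[1L] - 2L) * dt_ms
}

#' APD map from activation and repolarization maps
#'
#' `APD = RT - AT` where both are defined and positive; the sentinel
#' elsewhere.
#'
#' @param at_map,rt_map [scalar_map()]s of the same wave front.
#' @return a [scalar_map()] of APDs in ms.
#' @export
apd_map <- function(at_map, rt_map) {
  if (!identical(dim(at_map), dim(rt_map))) stop("map shapes differ")
  apd <- unclass(rt_map) - unclass(at_map)
  apd[!is.na(apd) & apd <= 0] <- NA_real_
  scalar_map(apd, units = "ms", pitch_mm = attr(at_map, "pitch_mm"))
}

#' Repolarization and APD maps of one wave front
#'
#' Two-pass scheme: repolarization times are first sought under the user APD
#' limits; the front's resolved APDs then refine the limits
#' ([refine_apd_limits()]) and a second pass produces the final maps.
#'
#' @param stack the preconditioned [voltage_stack()].
#' @param events an `activation_events` table.
#' @param labeling matching `wavefront_labeling`.
#' @param label_id wave-front label to map.
#' @param config a [repolarization_config()].
#' @return list: `at` (primary activation map), `rt`, `apd` maps, and the
#'   refined `limits` used.
#' @export
front_repolarization <- function(stack, events, labeling, label_id,
                                 config = repolarization_config()) {
  maps <- wavefront_at_maps(events, labeling, label_id)
  at <- maps$primary
  m <- stack_as_matrix(stack)
  d <- dim(stack$data)
  px <- which(!is.na(at))
  rt1 <- rep(NA_real_, length(px))
  for (j in seq_along(px)) {
    rt1[j] <- detect_repolarization(m[, px[j]], at[px[j]], config,
                                    dt_ms = stack$dt_ms)
  }
  lim <- refine_apd_limits(rt1 - at[px], config)
  rt <- matrix(NA_real_, d[1L], d[2L])
  for (j in seq_along(px)) {
    rt[px[j]] <- detect_repolarization(m[, px[j]], at[px[j]], config,
                                       limits = lim, dt_ms = stack$dt_ms)
  }
  rt <- scalar_map(rt, units = "ms", pitch_mm = stack$pitch_mm)
  list(at = at, rt = rt, apd = apd_map(at, rt), limits = lim)
}
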