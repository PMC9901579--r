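# Grouping activation events into wave fronts by space-time connectivity.

#' Wave-front grouping configuration
#'
#' @param theta_t_cb_ms conduction-block delay threshold in ms: the largest
#'   neighbor-to-neighbor activation delay still counted as propagation.
#' @param erp_min_ms minimum effective refractory period in ms: the shortest
#'   interval treated as genuine re-excitation of the same pixel.
#' @param theta_method,erp_method `"manual"` or `"auto"` provenance flags.
#' @param include_secondary should secondary (biphasic) components take part
#'   in labeling like primary ones (default `TRUE`).
#' @return a `wavefront_config` object.
#' @export
wavefront_config <- function(theta_t_cb_ms, erp_min_ms = NA_real_,
                             theta_method = "manual", erp_method = "manual",
                             include_secondary = TRUE) {
  if (theta_t_cb_ms <= 0) stop("theta_t_cb_ms must be > 0")
  if (!is.na(erp_min_ms) && erp_min_ms <= theta_t_cb_ms)
    warning("erp_min_ms is usually larger than theta_t_cb_ms")
  structure(list(theta_t_cb_ms = theta_t_cb_ms, erp_min_ms = erp_min_ms,
                 theta_method = theta_method, erp_method = erp_method,
                 include_secondary = include_secondary),
            class = "wavefront_config")
}

# nearest-in-time activation delays between 8-neighbor pixel pairs:
# one delay per (unordered pair, beat), rounded to the nearest 1 ms.
neighbor_delays_ms <- function(events) {
  ev <- data.table::as.data.table(events)[, list(x, y, t_ms)]
  offsets <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))
  delays <- numeric(0)
  for (off in offsets) {
    a <- data.table::copy(ev)
    b <- data.table::copy(ev)
    b[, `:=`(x = x - off[1L], y = y - off[2L], tb = t_ms)]
    data.table::setkey(b, x, y, tb)
    a[, ta := t_ms]
    m <- b[a, on = c("x", "y", "tb" = "ta"), roll = "nearest", nomatch = NULL,
           list(x, y, ta = i.t_ms, tb = x.tb)]
    if (nrow(m)) delays <- c(delays, abs(m$ta - m$tb))
  }
  round(delays)
}

#' Automated conduction-block threshold from a reference recording
#'
#' Estimated from an activation matrix of a progressively short-coupled
#' pacing train (S1S2...): all nearest-in-time activation delays between
#' 8-neighbor pixel pairs are binned at 1 ms, and \eqn{\theta_{t,CB}} is the
#' largest delay observed at least `n_short_stimuli` times - a slow pathway
#' crossed once per short-coupled stimulus produces exactly that count.
#'
#' Nearest-in-time pairing can mis-match beats when a neighbor's detection of
#' the same beat is missing: such delays are about one cycle length, not
#' conduction. Delays exceeding half the median same-pixel inter-activation
#' interval are therefore discarded before binning.
#'
#' @param reference an `activation_events` table from the reference recording.
#' @param n_short_stimuli number of short-coupled stimuli in the protocol.
#' @return `theta_t_cb_ms` (numeric, ms).
#' @export
estimate_conduction_block_threshold <- function(reference, n_short_stimuli) {
  if (n_short_stimuli < 1L) stop("n_short_stimuli must be >= 1")
  delays <- neighbor_delays_ms(reference)
  delays <- delays[delays > 0]
  ev <- data.table::as.data.table(reference)
  gaps <- ev[order(t_ms), diff(t_ms), by = pixel]$V1
  if (length(gaps)) delays <- delays[delays <= 0.5 * stats::median(gaps)]
  if (!length(delays))
    stop("no neighbor activation delays in reference; set theta manually")
  tab <- table(delays)
  qual <- as.numeric(names(tab))[tab >= n_short_stimuli]
  if (!length(qual))
    stop("no delay occurs >= ", n_short_stimuli,
         " times; set theta_t_cb manually")
  max(qual)
}

#' Label wave fronts by space-time connected components
#'
#' Two activation events are connected when their pixels are identical or
#' 8-adjacent and their activation times differ by at most
#' \eqn{\theta_{t,CB}} (closed interval). A wave front is a connected
#' component of this relation - converging fronts are deliberately one
#' object. Labels are contiguous integers assigned in scan order (fastest
#' through x, then y, then t) of each component's first event, matching the
#' queue-based flood formulation.
#'
#' @param events an `activation_events` table.
#' @param config a [wavefront_config()].
#' @return object of class `wavefront_labeling`: list with `label` (integer
#'   per event row), `info` (per-label metadata table), `config`.
#' @export
label_wavefronts <- function(events, config) {
  theta <- config$theta_t_cb_ms
  ev <- data.table::as.data.table(events)
  ev[, row0 := .I]
  if (!config$include_secondary) ev <- ev[component == "primary"]
  n <- nrow(ev)
  lab_full <- rep(NA_integer_, nrow(events))
  if (n == 0L) {
    return(structure(list(label = lab_full,
                          info = data.table::data.table(),
                          config = config), class = "wavefront_labeling"))
  }
  data.table::setorder(ev, t_ms, y, x)
  ev[, id := .I]
  edges <- connectivity_edges(ev, theta)
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::gorder(g)))
  comp <- igraph::components(g)$membership[seq_len(n)]
  # contiguous labels in first-event scan order (events already scan-sorted)
  first_seen <- !duplicated(comp)
  relabel <- integer(max(comp))
  relabel[comp[first_seen]] <- seq_len(sum(first_seen))
  lab <- relabel[comp]
  lab_full[ev$row0] <- lab
  info <- data.table::data.table(label = lab, t_ms = ev$t_ms, pixel = ev$pixel)[
    , list(n_events = .N, n_pixels = data.table::uniqueN(pixel),
           t_first_ms = min(t_ms), t_last_ms = max(t_ms),
           duration_ms = max(t_ms) - min(t_ms)), by = label]
  data.table::setorder(info, label)
  structure(list(label = lab_full, info = info, config = config),
            class = "wavefront_labeling")
}

# Edge list (pairs of scan-order event ids) of the space-time connectivity
# relation: same or 8-adjacent pixel, |dt| <= theta.
connectivity_edges <- function(ev, theta) {
  eg <- list()
  # same pixel: consecutive events within theta generate the same closure
  same <- ev[order(pixel, t_ms),
             list(a = id[-.N], b = id[-1L],
                  ok = diff(t_ms) <= theta), by = pixel]
  same <- same[ok == TRUE]
  if (nrow(same)) eg[[length(eg) + 1L]] <- cbind(same$a, same$b)
  offsets <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))
  a <- ev[, list(x, y, t_ms, id)]
  for (off in offsets) {
    b <- ev[, list(x = x - off[1L], y = y - off[2L], lo = t_ms - theta,
                   hi = t_ms + theta, idb = id)]
    data.table::setkey(b, x, y, lo, hi)
    a2 <- a[, list(x, y, lo = t_ms, hi = t_ms, ida = id)]
    data.table::setkey(a2, x, y, lo, hi)
    ov <- data.table::foverlaps(a2, b, type = "within", nomatch = NULL)
    if (nrow(ov)) eg[[length(eg) + 1L]] <- cbind(ov$ida, ov$idb)
  }
  if (!length(eg)) matrix(integer(0), ncol = 2L) else do.call(rbind, eg)
}

#' @export
print.wavefront_labeling <- function(x, ...) {
  cat(sprintf("<wavefront_labeling> %d wave fronts over %d events (theta = %g ms)\n",
              nrow(x$info), sum(!is.na(x$label)), x$config$theta_t_cb_ms))
  if (nrow(x$info)) print(x$info, topn = 5)
  invisible(x)
}

#' Primary and secondary activation maps of one wave front
#'
#' The primary map holds, per pixel, the earliest activation time carrying the
#' requested label. Where that upstroke was biphasic, the secondary map holds
#' the short-coupled second component (conserving locally dissociated
#' conduction); elsewhere it carries the sentinel.
#'
#' @param events an `activation_events` table.
#' @param labeling a `wavefront_labeling` for `events`.
#' @param label_id wave-front label number.
#' @return list of two [scalar_map()]s: `primary`, `secondary`.
#' @export
wavefront_at_maps <- function(events, labeling, label_id) {
  info <- labeling$info
  if (!label_id %in% info$label) stop("unknown wave-front label: ", label_id)
  d <- attr(events, "dims")
  ev <- data.table::as.data.table(events)
  ev[, label := labeling$label]
  evl <- ev[label == label_id]
  prim <- matrix(NA_real_, d[1L], d[2L])
  seco <- matrix(NA_real_, d[1L], d[2L])
  first <- evl[component == "primary", list(t_ms = min(t_ms),
                                            wid = window_id[which.min(t_ms)]),
               by = list(x, y, pixel)]
  prim[cbind(first$x, first$y)] <- first$t_ms
  sec <- evl[component == "secondary"]
  if (nrow(sec)) {
    sec <- merge(sec, first[, list(pixel, wid)],
                 by.x = c("pixel", "window_id"), by.y = c("pixel", "wid"))
    if (nrow(sec)) seco[cbind(sec$x, sec$y)] <- sec$t_ms
  }
  pitch <- attr(events, "pitch_mm") %||% NA_real_
  list(primary = scalar_map(prim, units = "ms", pitch_mm = pitch),
       secondary = scalar_map(seco, units = "ms", pitch_mm = pitch))
}

#' Export labeled events as CSV
#' @param events an `activation_events` table.
#' @param labeling matching `wavefront_labeling`.
#' @param path output path.
#' @export
write_labels_csv <- function(events, labeling, path) {
  out <- data.table::as.data.table(events)[, list(x, y, t_ms)]
  out[, label := labeling$label]
  data.table::fwrite(out, path)
  invisible(path)
}
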