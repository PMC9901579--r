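# Repetitiveness, activation origins, dynamic map stacks and classification
# of the conduction sources driving the leading wave front.

#' Default minimum effective refractory period
#'
#' When no short-coupled reference recording is available the minimum ERP is
#' estimated as 80% of the minimum basal action-potential duration.
#'
#' @param min_basal_apd_ms minimum APD during basal pacing, in ms.
#' @return ERPmin in ms.
#' @export
default_erp_min <- function(min_basal_apd_ms) 0.8 * min_basal_apd_ms

#' Classify a wave front as repetitive or non-repetitive
#'
#' Per pixel, the number of repetitions is the count of same-label activations
#' separated by at least `erp_min_ms` (greedy, in time order) minus one -
#' re-excitations faster than the minimum ERP are not genuine. The front is
#' repetitive when the histogram peak (mode) of the per-pixel repetition
#' counts is >= 1; a majority rule (> 50% of pixels repeating) is available
#' as an alternative.
#'
#' @param events an `activation_events` table.
#' @param labeling matching `wavefront_labeling`.
#' @param label_id wave-front label.
#' @param erp_min_ms minimum effective refractory period in ms.
#' @param rule `"histogram_peak"` (default) or `"majority"`.
#' @return list with `classification` (`"repetitive"`/`"non_repetitive"`),
#'   `repetition_map` ([scalar_map()] of counts), `histogram` (table), `rule`.
#' @export
classify_repetitiveness <- function(events, labeling, label_id, erp_min_ms,
                                    rule = c("histogram_peak", "majority")) {
  rule <- match.arg(rule)
  if (!label_id %in% labeling$info$label) stop("unknown label: ", label_id)
  d <- attr(events, "dims")
  ev <- data.table::as.data.table(events)
  ev[, label := labeling$label]
  evl <- ev[label == label_id]
  reps <- evl[order(t_ms), list(reps = {
    n_acc <- 0L; last <- -Inf
    for (tt in t_ms) if (tt - last >= erp_min_ms) { n_acc <- n_acc + 1L; last <- tt }
    max(0L, n_acc - 1L)
  }), by = list(x, y)]
  mp <- matrix(NA_real_, d[1L], d[2L])
  mp[cbind(reps$x, reps$y)] <- reps$reps
  hist <- table(reps$reps)
  mode_val <- max(as.integer(names(hist)[hist == max(hist)]))
  repetitive <- if (rule == "histogram_peak") mode_val >= 1L
                else mean(reps$reps >= 1L) > 0.5
  list(classification = if (repetitive) "repetitive" else "non_repetitive",
       repetition_map = scalar_map(mp, units = "count",
                                   pitch_mm = attr(events, "pitch_mm")),
       histogram = hist, rule = rule)
}

#' Detect activation origins (breakthrough and passive) of a wave front
#'
#' Activation origins are local activation-time minima: events with no
#' preceding same-label event within `erp_min_ms` anywhere in their local
#' 8-point neighborhood (own pixel included). Minima are spatially grouped by
#' connected components together with their simultaneously activated
#' continuation (time tolerance `sim_tol_ms`); a cluster containing any point
#' that *is* preceded within the ERP window is a false positive fed from a
#' peripheral source and is rejected wholesale. Surviving clusters are typed
#' `passive` when they touch the mask periphery (image border or a
#' masked-out pixel), `breakthrough` otherwise; the centroid is the rounded
#' mean of the member coordinates.
#'
#' @param events an `activation_events` table.
#' @param labeling matching `wavefront_labeling`.
#' @param label_id wave-front label.
#' @param erp_min_ms minimum effective refractory period in ms.
#' @param mask logical ROI matrix (`[x, y]`).
#' @param sim_tol_ms time tolerance defining "simultaneous" cluster growth
#'   (default 0: same frame).
#' @return object of class `origin_set`: list with `clusters` (table:
#'   `cluster`, `type`, `centroid_x`, `centroid_y`, `beat_t_ms`, `size`),
#'   `members`, `occurrence` and `centroid_map` ([scalar_map()]s of counts).
#' @export
detect_activation_origins <- function(events, labeling, label_id, erp_min_ms,
                                      mask, sim_tol_ms = 0) {
  if (!label_id %in% labeling$info$label) stop("unknown label: ", label_id)
  d <- attr(events, "dims"); nx <- d[1L]; ny <- d[2L]
  ev <- data.table::as.data.table(events)
  ev[, label := labeling$label]
  evl <- ev[label == label_id, list(x, y, t_ms)]
  evl[, id := .I]

  preceded <- rep(FALSE, nrow(evl))
  b <- evl[, list(x, y, tb = t_ms)]
  for (dx in -1:1) for (dy in -1:1) {
    a <- evl[, list(x = x + dx, y = y + dy, lo = t_ms - erp_min_ms,
                    hi = t_ms, id)]
    mtch <- b[a, on = c("x", "y", "tb >= lo", "tb < hi"), nomatch = NULL,
              list(id = i.id)]
    if (nrow(mtch)) preceded[unique(mtch$id)] <- TRUE
  }
  candidate <- !preceded

  # simultaneity components over all label events (8-adjacency, |dt| <= tol)
  eg <- list()
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))) {
    bb <- evl[, list(x = x - off[1L], y = y - off[2L], lo = t_ms - sim_tol_ms,
                     hi = t_ms + sim_tol_ms, idb = id)]
    data.table::setkey(bb, x, y, lo, hi)
    aa <- evl[, list(x, y, lo = t_ms, hi = t_ms, ida = id)]
    data.table::setkey(aa, x, y, lo, hi)
    ov <- data.table::foverlaps(aa, bb, type = "within", nomatch = NULL)
    if (nrow(ov)) eg[[length(eg) + 1L]] <- cbind(ov$ida, ov$idb)
  }
  edges <- if (length(eg)) do.call(rbind, eg) else matrix(integer(0), ncol = 2L)
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nrow(evl) - igraph::gorder(g)))
  comp <- igraph::components(g)$membership[seq_len(nrow(evl))]

  keep_comp <- vapply(split(candidate, comp), all, logical(1L))
  has_cand <- vapply(split(candidate, comp), any, logical(1L))
  kept <- as.integer(names(keep_comp))[keep_comp & has_cand]

  periphery <- periphery_mask(mask)
  occ <- matrix(0, nx, ny); cen <- matrix(0, nx, ny)
  clusters <- list(); members <- list()
  cid <- 0L
  for (cp in kept) {
    mem <- evl[comp == cp]
    cid <- cid + 1L
    type <- if (any(periphery[cbind(mem$x, mem$y)])) "passive" else "breakthrough"
    cx <- as.integer(round(mean(mem$x))); cy <- as.integer(round(mean(mem$y)))
    clusters[[cid]] <- data.table::data.table(
      cluster = cid, type = type, centroid_x = cx, centroid_y = cy,
      beat_t_ms = min(mem$t_ms), size = nrow(unique(mem[, list(x, y)])))
    members[[cid]] <- data.table::data.table(cluster = cid, type = type,
                                             x = mem$x, y = mem$y,
                                             t_ms = mem$t_ms)
    upx <- unique(mem[, list(x, y)])
    occ[cbind(upx$x, upx$y)] <- occ[cbind(upx$x, upx$y)] + 1
    cen[cx, cy] <- cen[cx, cy] + 1
  }
  clusters <- if (cid) data.table::rbindlist(clusters) else
    data.table::data.table(cluster = integer(0), type = character(0),
                           centroid_x = integer(0), centroid_y = integer(0),
                           beat_t_ms = numeric(0), size = integer(0))
  members <- if (cid) data.table::rbindlist(members) else
    data.table::data.table(cluster = integer(0), type = character(0),
                           x = integer(0), y = integer(0), t_ms = numeric(0))
  structure(list(clusters = clusters, members = members,
                 occurrence = scalar_map(occ, units = "count"),
                 centroid_map = scalar_map(cen, units = "count")),
            class = "origin_set")
}

# pixels 8-adjacent to the image border or to a masked-out pixel
periphery_mask <- function(mask) {
  nx <- nrow(mask); ny <- ncol(mask)
  out <- matrix(FALSE, nx, ny)
  out[1L, ] <- out[nx, ] <- TRUE
  out[, 1L] <- out[, ny] <- TRUE
  if (any(!mask)) {
    bad <- which(!mask, arr.ind = TRUE)
    for (k in seq_len(nrow(bad))) {
      xs <- max(1L, bad[k, 1L] - 1L):min(nx, bad[k, 1L] + 1L)
      ys <- max(1L, bad[k, 2L] - 1L):min(ny, bad[k, 2L] + 1L)
      out[xs, ys] <- TRUE
    }
  }
  out & mask
}

#' @export
print.origin_set <- function(x, ...) {
  cat(sprintf("<origin_set> %d clusters (%d breakthrough, %d passive)\n",
              nrow(x$clusters), sum(x$clusters$type == "breakthrough"),
              sum(x$clusters$type == "passive")))
  invisible(x)
}

#' Dynamic map stack of a complex activation (or repolarization) sequence
#'
#' A single map per wave front hides re-excitation; a dynamic stack tiles the
#' episode instead. The first map fills pixels with time points advancing in
#' time until a pixel would be filled twice; every subsequent map starts as a
#' copy of its predecessor and overwrites forward in time until its own
#' collision. Every event in the probed window appears in exactly one map as
#' a fresh write.
#'
#' @param events an `activation_events` table or any data.frame with columns
#'   `x`, `y`, `t_ms` (e.g. repolarization events).
#' @param window_ms half-open `c(t0, t1)` probe window in ms (default: all).
#' @param dims spatial dims `c(nx, ny)`; taken from `events` attributes when
#'   available.
#' @return object of class `dynamic_map_stack`: list with `maps` (list of
#'   [scalar_map()]), `spans` (per-map first/last fresh time and count), and
#'   `map_index` (map number of each event in the probed window).
#' @export
dynamic_map_stack <- function(events, window_ms = NULL, dims = NULL) {
  d <- dims %||% attr(events, "dims")
  if (is.null(d)) stop("spatial dims unknown; pass dims = c(nx, ny)")
  nx <- d[1L]; ny <- d[2L]
  ev <- data.table::as.data.table(events)[, list(x, y, t_ms)]
  if (!is.null(window_ms)) {
    if (window_ms[1L] >= window_ms[2L]) stop("empty probe window")
    ev <- ev[t_ms >= window_ms[1L] & t_ms < window_ms[2L]]
  }
  data.table::setorder(ev, t_ms, y, x)
  n <- nrow(ev)
  maps <- list(); spans <- list()
  cur <- matrix(NA_real_, nx, ny)
  fresh <- matrix(FALSE, nx, ny)
  midx <- integer(n)
  t_start <- NA_real_; nf <- 0L
  for (i in seq_len(n)) {
    xx <- ev$x[i]; yy <- ev$y[i]
    if (fresh[xx, yy]) {                      # collision: close this map
      maps[[length(maps) + 1L]] <- cur
      spans[[length(spans) + 1L]] <- c(t_start, ev$t_ms[i - 1L], nf)
      fresh[] <- FALSE                        # next map inherits cur values
      t_start <- NA_real_; nf <- 0L
    }
    cur[xx, yy] <- ev$t_ms[i]
    fresh[xx, yy] <- TRUE
    if (is.na(t_start)) t_start <- ev$t_ms[i]
    nf <- nf + 1L
    midx[i] <- length(maps) + 1L
  }
  if (nf > 0L || !length(maps)) {
    maps[[length(maps) + 1L]] <- cur
    spans[[length(spans) + 1L]] <- c(t_start, if (n) ev$t_ms[n] else NA_real_, nf)
  }
  spans <- data.table::as.data.table(do.call(rbind, spans))
  data.table::setnames(spans, c("t_first_ms", "t_last_ms", "n_fresh"))
  spans[, map := .I]
  structure(list(maps = lapply(maps, scalar_map, units = "ms"),
                 spans = spans, map_index = midx, events = ev),
            class = "dynamic_map_stack")
}

#' @export
print.dynamic_map_stack <- function(x, ...) {
  cat(sprintf("<dynamic_map_stack> %d maps, %d events\n",
              length(x$maps), length(x$map_index)))
  invisible(x)
}

#' Unit conduction-direction field of an activation map
#'
#' Local propagation direction normal to the isochrones: the spatial gradient
#' of activation time from a least-squares plane fit over the defined pixels
#' of a 3x3 window (expanded to 5x5 where 3x3 is rank-deficient), normalized
#' to unit length. Undefined (NA) where the fit fails or the gradient
#' vanishes (simultaneous activation).
#'
#' @param map a [scalar_map()] of activation times.
#' @param pitch_mm pixel pitch; defaults to the map attribute.
#' @return list with unit components `ux`, `uy` and gradient magnitude
#'   `grad_ms_per_mm`.
#' @export
conduction_vector_field <- function(map, pitch_mm = NULL) {
  pitch <- pitch_mm %||% attr(map, "pitch_mm")
  if (is.null(pitch) || is.na(pitch)) pitch <- 1
  z <- unclass(map)
  nx <- nrow(z); ny <- ncol(z)
  ux <- uy <- gm <- matrix(NA_real_, nx, ny)
  fit_grad <- function(x0, y0, h) {
    xs <- max(1L, x0 - h):min(nx, x0 + h)
    ys <- max(1L, y0 - h):min(ny, y0 + h)
    sub <- z[xs, ys, drop = FALSE]
    ok <- which(!is.na(sub), arr.ind = TRUE)
    if (nrow(ok) < 3L) return(NULL)
    dx <- xs[ok[, 1L]] - x0; dy <- ys[ok[, 2L]] - y0
    A <- cbind(1, dx, dy)
    qa <- qr(A)
    if (qa$rank < 3L) return(NULL)
    qr.coef(qa, sub[ok])[2:3]
  }
  for (x0 in seq_len(nx)) for (y0 in seq_len(ny)) {
    if (is.na(z[x0, y0])) next
    g <- fit_grad(x0, y0, 1L)
    if (is.null(g)) g <- fit_grad(x0, y0, 2L)
    if (is.null(g) || any(!is.finite(g))) next
    nrm <- sqrt(sum(g^2))
    if (nrm < 1e-9) next
    ux[x0, y0] <- g[1L] / nrm
    uy[x0, y0] <- g[2L] / nrm
    gm[x0, y0] <- nrm / pitch
  }
  list(ux = ux, uy = uy, grad_ms_per_mm = gm)
}

# does the ray from (xn, yn) along unit (vx, vy) pass within `tol` pixels of
# (xc, yc)?
ray_intersects <- function(xn, yn, vx, vy, xc, yc, tol = 0.5) {
  wx <- xc - xn; wy <- yc - yn
  proj <- wx * vx + wy * vy
  if (proj < 0) return(FALSE)
  d2 <- wx * wx + wy * wy - proj * proj
  d2 <= tol * tol + 1e-12
}

#' Conduction fields of the leading wave-front points
#'
#' Leading points are the local activation-time maxima of the probed dynamic
#' map (the most recently activated sites along the advancing front edges).
#' For each leading point the full upstream tissue area that conducted into
#' it (its conduction field) is recovered by a backward flood over defined
#' 8-neighbors within `(t - theta_t_cb_ms, t]`, keeping only neighbors whose
#' local conduction-vector ray intersects the pixel they feed (within half a
#' pixel).
#'
#' @param map one [scalar_map()] from a [dynamic_map_stack()].
#' @param vectors matching [conduction_vector_field()].
#' @param theta_t_cb_ms conduction-block threshold in ms.
#' @return list of conduction fields; each has `leading = c(x, y, t_ms)` and
#'   `points`, a table `(x, y, t_ms, n_back, n_intersecting)` where `n_back`
#'   counts upstream temporal neighbors and `n_intersecting` those whose
#'   conduction vector intersects the point.
#' @export
leading_front_conduction_fields <- function(map, vectors, theta_t_cb_ms) {
  z <- unclass(map)
  nx <- nrow(z); ny <- ncol(z)
  lead <- list()
  for (x0 in seq_len(nx)) for (y0 in seq_len(ny)) {
    t0 <- z[x0, y0]
    if (is.na(t0)) next
    xs <- max(1L, x0 - 1L):min(nx, x0 + 1L)
    ys <- max(1L, y0 - 1L):min(ny, y0 + 1L)
    nb <- z[xs, ys]
    if (all(is.na(nb)) || t0 >= max(nb, na.rm = TRUE))
      lead[[length(lead) + 1L]] <- c(x0, y0, t0)
  }
  lapply(lead, function(lp) {
    x0 <- lp[1L]; y0 <- lp[2L]
    visited <- matrix(FALSE, nx, ny)
    visited[x0, y0] <- TRUE
    queue <- list(c(x0, y0))
    pts <- list()
    while (length(queue)) {
      cc <- queue[[1L]]; queue <- queue[-1L]
      xc <- cc[1L]; yc <- cc[2L]; tc <- z[xc, yc]
      nback <- 0L; ninter <- 0L
      for (dx in -1:1) for (dy in -1:1) {
        if (dx == 0L && dy == 0L) next
        xn <- xc + dx; yn <- yc + dy
        if (xn < 1L || xn > nx || yn < 1L || yn > ny) next
        tn <- z[xn, yn]
        if (is.na(tn) || tn > tc || tn <= tc - theta_t_cb_ms) next
        if (xn == x0 && yn == y0) next
        nback <- nback + 1L
        vx <- vectors$ux[xn, yn]; vy <- vectors$uy[xn, yn]
        if (is.na(vx)) next
        if (ray_intersects(xn, yn, vx, vy, xc, yc)) {
          ninter <- ninter + 1L
          if (!visited[xn, yn]) {
            visited[xn, yn] <- TRUE
            queue[[length(queue) + 1L]] <- c(xn, yn)
          }
        }
      }
      pts[[length(pts) + 1L]] <- c(xc, yc, tc, nback, ninter)
    }
    pts <- data.table::as.data.table(do.call(rbind, pts))
    data.table::setnames(pts, c("x", "y", "t_ms", "n_back", "n_intersecting"))
    list(leading = lp, points = pts)
  })
}

#' Classify the conduction sources of the leading wave front
#'
#' Each leading point's conduction field is tested against five criteria (a
#' field may satisfy several; all are recorded):
#' \enumerate{
#'   \item breakthrough - the field co-localizes with a breakthrough origin;
#'   \item passive - the field co-localizes with a passive (periphery) origin;
#'   \item myocardial reentry - two 8-adjacent field points differ in
#'     activation time by more than `erp_min_ms` (re-excitation through the
#'     field itself);
#'   \item tortuous propagation - a field point has upstream temporal
#'     neighbors but none with an intersecting conduction vector
#'     (discontinuous local path);
#'   \item wave-front boundary - a field point without intersecting
#'     conduction-field neighbors is adjacent to activation from a different
#'     wave-front label (requires `label_map`).
#' }
#'
#' @param fields result of [leading_front_conduction_fields()].
#' @param origins an `origin_set` for the same episode.
#' @param erp_min_ms minimum effective refractory period in ms.
#' @param theta_t_cb_ms conduction-block threshold in ms (co-localization
#'   time tolerance).
#' @param label_map optional integer matrix of wave-front labels per pixel
#'   for the probed window (needed for the boundary class).
#' @return object of class `source_classification`: list with `per_point`
#'   (leading point coordinates and classes), `counts` and `percentages`
#'   (normalized to 100 over all class assignments).
#' @export
classify_front_sources <- function(fields, origins, erp_min_ms,
                                   theta_t_cb_ms, label_map = NULL) {
  classes <- c("breakthrough", "passive", "myocardial_reentry",
               "tortuous", "boundary")
  bt <- origins$members[origins$members$type == "breakthrough"]
  pv <- origins$members[origins$members$type == "passive"]
  per <- lapply(fields, function(f) {
    p <- f$points
    got <- character(0)
    # co-localization within one pixel (the conduction field cannot enter
    # pixels whose conduction vector is undefined, e.g. the flat core of a
    # focal origin, so exact pixel identity would miss true breakthroughs)
    colocal <- function(org) {
      if (!nrow(org) || !nrow(p)) return(FALSE)
      for (dx in -1:1) for (dy in -1:1) {
        o <- data.table::data.table(x = org$x + dx, y = org$y + dy,
                                    t_o = org$t_ms)
        m <- merge(p, o, by = c("x", "y"), allow.cartesian = TRUE)
        if (nrow(m) && any(abs(m$t_ms - m$t_o) <= theta_t_cb_ms))
          return(TRUE)
      }
      FALSE
    }
    if (colocal(bt)) got <- c(got, "breakthrough")
    if (colocal(pv)) got <- c(got, "passive")
    # adjacent field points with activation difference beyond the ERP
    if (nrow(p) > 1L) {
      reent <- FALSE
      for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))) {
        b <- p[, list(x = x - off[1L], y = y - off[2L], tb = t_ms)]
        m <- merge(p, b, by = c("x", "y"))
        if (nrow(m) && any(abs(m$t_ms - m$tb) > erp_min_ms)) { reent <- TRUE; break }
      }
      if (reent) got <- c(got, "myocardial_reentry")
    }
    if (any(p$n_back > 0L & p$n_intersecting == 0L)) got <- c(got, "tortuous")
    if (!is.null(label_map)) {
      cand <- p[p$n_intersecting == 0L]
      bdry <- FALSE
      if (nrow(cand)) {
        nxl <- nrow(label_map); nyl <- ncol(label_map)
        for (i in seq_len(nrow(cand))) {
          own <- label_map[cand$x[i], cand$y[i]]
          for (dx in -1:1) for (dy in -1:1) {
            xn <- cand$x[i] + dx; yn <- cand$y[i] + dy
            if ((dx | dy) && xn >= 1L && xn <= nxl && yn >= 1L && yn <= nyl &&
                !is.na(label_map[xn, yn]) && !is.na(own) &&
                label_map[xn, yn] != own) bdry <- TRUE
          }
        }
      }
      if (bdry) got <- c(got, "boundary")
    }
    got
  })
  counts <- vapply(classes, function(cl)
    sum(vapply(per, function(g) cl %in% g, logical(1L))), numeric(1L))
  tot <- sum(counts)
  pct <- if (tot > 0) 100 * counts / tot else counts * NA_real_
  per_point <- data.table::data.table(
    x = vapply(fields, function(f) f$leading[1L], numeric(1L)),
    y = vapply(fields, function(f) f$leading[2L], numeric(1L)),
    t_ms = vapply(fields, function(f) f$leading[3L], numeric(1L)),
    classes = vapply(per, function(g)
      if (length(g)) paste(g, collapse = ";") else "unclassified", character(1L)))
  structure(list(per_point = per_point, counts = counts, percentages = pct),
            class = "source_classification")
}

#' Export a source classification report as JSON
#'
#' Per-class counts and percentages plus the per-leading-point assignments.
#' @param classification a `source_classification`.
#' @param path output path.
#' @export
write_classification_json <- function(classification, path) {
  jsonlite::write_json(
    list(counts = as.list(classification$counts),
         percentages = as.list(classification$percentages),
         per_point = classification$per_point),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}

#' Export a dynamic map stack as a numbered CSV (and optional PNG) series
#'
#' Writes `<prefix>_001.csv`, `<prefix>_002.csv`, ... one file per map.
#' @param stack a `dynamic_map_stack`.
#' @param prefix path prefix (directory must exist).
#' @param png also render PNG isochrone images (default `FALSE`).
#' @export
write_dynamic_stack <- function(stack, prefix, png = FALSE) {
  for (i in seq_along(stack$maps)) {
    write_map_csv(stack$maps[[i]], sprintf("%s_%03d.csv", prefix, i))
    if (png) write_map_png(stack$maps[[i]], sprintf("%s_%03d.png", prefix, i))
  }
  invisible(prefix)
}

#' @export
print.source_classification <- function(x, ...) {
  cat("<source_classification>\n")
  for (nm in names(x$counts))
    cat(sprintf("  %-20s %4d (%.1f%%)\n", nm, x$counts[[nm]],
                x$percentages[[nm]]))
  invisible(x)
}
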