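# Ground-truthed synthetic optical-mapping stacks from a two-variable
# excitable medium (Aliev-Panfilov-type reaction-diffusion) with an optical
# observation model. Stands in for monodomain ionic simulations at desk scale:
# the analysis pipeline only needs realistic activation/repolarization
# morphology, not ionic fidelity.

#' Define a simulation scenario
#'
#' The excitable sheet follows the two-variable phenomenological model
#' \deqn{du/dt = -k u (u-a)(u-1) - u v + D \nabla^2 u}
#' \deqn{dv/dt = (\epsilon_0 + \mu_1 v / (u + \mu_2)) (-v - k u (u-a-1))}
#' integrated explicitly on a `nx x ny` grid with no-flux boundaries.
#' Model time is scaled to ms by `time_scale_ms` (the classical 12.9 ms per
#' model time unit).
#'
#' @param nx,ny grid size in pixels.
#' @param duration_ms recording duration in ms.
#' @param dt_ms frame interval in ms (1 kHz default).
#' @param pitch_mm pixel pitch in mm.
#' @param stimuli list of stimulus descriptors, each a list with `kind`
#'   (`"planar_edge"`, `"point"` or `"cross_field"`), `time_ms`, and geometry:
#'   `side` + `width_px` (planar), `x`,`y`,`radius_px` (point), `side` +
#'   `frac` (cross-field half-plane).
#' @param params model parameters (`k`, `a`, `eps0`, `mu1`, `mu2`, `D`,
#'   `dt_model`, `time_scale_ms`); defaults give a sustained spiral on a
#'   100 x 100 sheet.
#' @param seed integer RNG seed; fixed seed gives bitwise-reproducible output.
#' @return a `sim_scenario` object.
#' @export
sim_scenario <- function(nx = 100L, ny = 100L, duration_ms = 4000,
                         dt_ms = 1, pitch_mm = 0.7, stimuli = list(),
                         params = list(), seed = 1L) {
  p <- utils::modifyList(list(k = 8, a = 0.1, eps0 = 0.01, mu1 = 0.14,
                              mu2 = 0.3, D = 0.5, dt_model = 0.02,
                              time_scale_ms = 12.9), params)
  for (st in stimuli) {
    if (!st$kind %in% c("planar_edge", "point", "cross_field"))
      stop("unknown stimulus kind: ", st$kind)
    if (st$time_ms < 0 || st$time_ms >= duration_ms)
      stop("stimulus outside the recording")
    if (st$kind == "point" &&
        (st$x < 1 || st$x > nx || st$y < 1 || st$y > ny))
      stop("point stimulus outside the grid")
  }
  structure(list(nx = as.integer(nx), ny = as.integer(ny),
                 duration_ms = duration_ms, dt_ms = dt_ms,
                 pitch_mm = pitch_mm, stimuli = stimuli, params = p,
                 seed = as.integer(seed)),
            class = "sim_scenario")
}

#' Read / write a simulation scenario as JSON
#'
#' @param scenario a [sim_scenario()].
#' @param path JSON file path.
#' @return [read_scenario()] returns a `sim_scenario`;
#'   [write_scenario()] returns `path` invisibly.
#' @export
write_scenario <- function(scenario, path) {
  jsonlite::write_json(unclass(scenario), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  v <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  sim_scenario(nx = v$nx, ny = v$ny, duration_ms = v$duration_ms,
               dt_ms = v$dt_ms, pitch_mm = v$pitch_mm,
               stimuli = v$stimuli %||% list(), params = v$params %||% list(),
               seed = v$seed %||% 1L)
}

stimulus_region <- function(st, nx, ny) {
  reg <- matrix(FALSE, nx, ny)
  if (st$kind == "planar_edge") {
    w <- st$width_px %||% 3L
    switch(st$side %||% "xmin",
           xmin = { reg[seq_len(w), ] <- TRUE },
           xmax = { reg[(nx - w + 1L):nx, ] <- TRUE },
           ymin = { reg[, seq_len(w)] <- TRUE },
           ymax = { reg[, (ny - w + 1L):ny] <- TRUE })
  } else if (st$kind == "point") {
    r <- st$radius_px %||% 2L
    xs <- matrix(seq_len(nx), nx, ny); ys <- matrix(seq_len(ny), nx, ny, byrow = TRUE)
    reg <- (xs - st$x)^2 + (ys - st$y)^2 <= r^2
  } else if (st$kind == "cross_field") {
    frac <- st$frac %||% 0.5
    switch(st$side %||% "ylow",
           ylow = { reg[, seq_len(max(1L, floor(ny * frac)))] <- TRUE },
           yhigh = { reg[, (ny - max(1L, floor(ny * frac)) + 1L):ny] <- TRUE },
           xlow = { reg[seq_len(max(1L, floor(nx * frac))), ] <- TRUE },
           xhigh = { reg[(nx - max(1L, floor(nx * frac)) + 1L):nx, ] <- TRUE })
  }
  reg
}

#' Simulate an excitable sheet and extract the electrical ground truth
#'
#' Deterministic explicit integration of the scenario's reaction-diffusion
#' model; frames of the excitation variable are recorded every `dt_ms`.
#' Ground-truth electrical activation times (eAT) are the upward crossings of
#' the excitation variable at 50% of its global range (linearly interpolated
#' between frames); any fixed threshold gives the same activation ordering
#' for monotone upstrokes.
#'
#' @param scenario a [sim_scenario()].
#' @return list with `membrane` (a [voltage_stack()] of the excitation
#'   variable) and `truth` (class `ground_truth`: `events` table of eAT,
#'   `origins`, `period_ms` of sustained activity at a probe pixel if any,
#'   `apd_ms` map of the first beat).
#' @export
simulate_excitable_sheet <- function(scenario) {
  p <- scenario$params
  nx <- scenario$nx; ny <- scenario$ny
  if (p$dt_model > 1 / (4 * p$D))
    stop("CFL violation: dt_model must be <= 1/(4 D) for stability")
  frame_model <- scenario$dt_ms / p$time_scale_ms   # model time per frame
  nsub <- max(1L, as.integer(ceiling(frame_model / p$dt_model)))
  dtm <- frame_model / nsub
  nt <- as.integer(round(scenario$duration_ms / scenario$dt_ms))
  u <- matrix(0, nx, ny); v <- matrix(0, nx, ny)
  stim <- scenario$stimuli
  stim_frame <- vapply(stim, function(s)
    as.integer(round(s$time_ms / scenario$dt_ms)) + 1L, integer(1L))
  arr <- array(0, dim = c(nx, ny, nt))
  for (fr in seq_len(nt)) {
    hit <- which(stim_frame == fr)
    for (h in hit) {
      reg <- stimulus_region(stim[[h]], nx, ny)
      amp <- stim[[h]]$amplitude %||% 1
      u[reg] <- pmax(u[reg], amp)
    }
    arr[, , fr] <- u
    .ap_advance(u, v, nsub, dtm, p$k, p$a, p$eps0, p$mu1, p$mu2, p$D)
  }
  membrane <- voltage_stack(arr, dt_ms = scenario$dt_ms,
                            pitch_mm = scenario$pitch_mm,
                            meta = list(kind = "membrane",
                                        scenario = scenario[
                                          c("nx", "ny", "duration_ms",
                                            "dt_ms", "seed")]))
  truth <- extract_ground_truth(membrane, scenario)
  list(membrane = membrane, truth = truth)
}

# eAT events from threshold crossings of the excitation variable
extract_ground_truth <- function(membrane, scenario) {
  arr <- membrane$data
  d <- dim(arr); nx <- d[1L]; ny <- d[2L]; nt <- d[3L]
  thr <- min(arr) + 0.5 * (max(arr) - min(arr))
  m <- stack_as_matrix(membrane)
  # all upward threshold crossings at once (vectorized over pixels)
  below <- m < thr
  cross <- which(!below[-1L, , drop = FALSE] & below[-nt, , drop = FALSE])
  r <- ((cross - 1L) %% (nt - 1L)) + 1L          # frame before the crossing
  px <- ((cross - 1L) %/% (nt - 1L)) + 1L
  frac <- (thr - m[cbind(r, px)]) / (m[cbind(r + 1L, px)] - m[cbind(r, px)])
  events <- data.table::data.table(
    x = ((px - 1L) %% nx) + 1L, y = ((px - 1L) %/% nx) + 1L,
    t_ms = (r - 1L + frac) * membrane$dt_ms, pixel = px)
  data.table::setorder(events, t_ms, y, x)
  data.table::setattr(events, "dims", d)
  data.table::setattr(events, "dt_ms", membrane$dt_ms)
  data.table::setattr(events, "pitch_mm", membrane$pitch_mm)
  # sustained-activity period at the most-reactivated pixel
  period <- NA_real_
  if (nrow(events)) {
    cnt <- events[, .N, by = pixel]
    probe <- cnt$pixel[which.max(cnt$N)]
    tt <- sort(events[pixel == probe, t_ms])
    if (length(tt) >= 3L) period <- stats::median(diff(tt))
  }
  # APD (time above threshold) of the first beat per pixel
  apd <- matrix(NA_real_, nx, ny)
  if (nrow(events)) {
    first <- events[, list(t0 = min(t_ms)), by = pixel]
    for (j in seq_len(nrow(first))) {
      p0 <- first$pixel[j]
      i0 <- as.integer(ceiling(first$t0[j] / membrane$dt_ms)) + 1L
      dn <- which(below[(i0 + 1L):nt, p0])
      if (length(dn))
        apd[p0] <- (i0 + dn[1L] - 1L) * membrane$dt_ms - first$t0[j]
    }
  }
  origins <- lapply(scenario$stimuli, function(st)
    list(kind = st$kind, time_ms = st$time_ms,
         x = st$x %||% NA, y = st$y %||% NA))
  structure(list(events = events, origins = origins, period_ms = period,
                 apd_ms = scalar_map(apd, units = "ms",
                                     pitch_mm = membrane$pitch_mm)),
            class = "ground_truth")
}

#' Emulate epi-fluorescent optical observation of a membrane stack
#'
#' Optical mapping integrates a near-surface tissue volume: the membrane
#' excitation is spatially blurred (Gaussian), inverted (fluorescence falls
#' on depolarization), optionally given a linear baseline drift, and
#' corrupted with additive white Gaussian noise scaled so that the measured
#' signal-to-noise ratio (under the preprocessing module's definition:
#' peak-to-peak of the sub-60 Hz signal over the noise SD above 60 Hz)
#' matches `snr_target`.
#'
#' @param membrane a [voltage_stack()] from [simulate_excitable_sheet()].
#' @param blur_sigma_px Gaussian blur SD in pixels (0 disables).
#' @param snr_target target SNR (`Inf` disables noise).
#' @param drift_per_s linear baseline drift in normalized units per second.
#' @param seed RNG seed for the noise.
#' @return a raw (un-preconditioned, inverted) [voltage_stack()].
#' @export
emulate_optical_observation <- function(membrane, blur_sigma_px = 1,
                                        snr_target = Inf, drift_per_s = 0,
                                        seed = 1L) {
  if (blur_sigma_px < 0) stop("blur_sigma_px must be >= 0")
  if (snr_target <= 0) stop("snr_target must be > 0")
  arr <- membrane$data
  d <- dim(arr); nt <- d[3L]
  if (blur_sigma_px > 0) arr <- gaussian_blur_xy(arr, blur_sigma_px)
  arr <- 1 - arr                                   # inversion
  if (drift_per_s != 0) {
    drift <- drift_per_s * (seq_len(nt) - 1L) * membrane$dt_ms / 1000
    arr <- arr + rep(drift, each = d[1L] * d[2L])
  }
  if (is.finite(snr_target)) {
    fs <- 1000 / membrane$dt_ms
    amp <- stats::median(apply(matrix(arr, d[1L] * d[2L], nt), 1L,
                               function(v) diff(range(v))))
    frac_above <- max(1e-6, (fs / 2 - 60) / (fs / 2))
    sigma_n <- amp / (snr_target * sqrt(frac_above))
    set.seed(seed)
    arr <- arr + array(stats::rnorm(length(arr), sd = sigma_n), dim = d)
  }
  voltage_stack(arr, dt_ms = membrane$dt_ms, pitch_mm = membrane$pitch_mm,
                meta = list(kind = "optical", blur_sigma_px = blur_sigma_px,
                            snr_target = snr_target,
                            drift_per_s = drift_per_s, seed = seed))
}

# separable Gaussian blur of each frame, kernel renormalized at borders
gaussian_blur_xy <- function(arr, sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  kern <- stats::dnorm(-r:r, sd = sigma)
  d <- dim(arr)
  blur_axis <- function(a, axis) {
    acc <- array(0, dim(a)); wacc <- array(0, dim(a))
    n <- dim(a)[axis]
    for (k in -r:r) {
      src <- max(1L, 1L - k):min(n, n - k)
      dst <- src + k
      w <- kern[k + r + 1L]
      if (axis == 1L) {
        acc[dst, , ] <- acc[dst, , , drop = FALSE] + w * a[src, , , drop = FALSE]
        wacc[dst, , ] <- wacc[dst, , , drop = FALSE] + w
      } else {
        acc[, dst, ] <- acc[, dst, , drop = FALSE] + w * a[, src, , drop = FALSE]
        wacc[, dst, ] <- wacc[, dst, , drop = FALSE] + w
      }
    }
    acc / wacc
  }
  blur_axis(blur_axis(arr, 1L), 2L)
}

#' Spatially downsample a stack (image-resolution sweep)
#'
#' Block-averages pixels into bins of (possibly fractional) `factor`,
#' emulating acquisition at a coarser pixel pitch.
#'
#' @param stack a [voltage_stack()].
#' @param factor downsampling factor (>= 1; 2.5 emulates 0.7 -> 1.75 mm).
#' @return a downsampled [voltage_stack()].
#' @export
downsample_stack <- function(stack, factor) {
  if (factor < 1) stop("factor must be >= 1")
  d <- dim(stack$data); nx <- d[1L]; ny <- d[2L]; nt <- d[3L]
  bx <- floor((seq_len(nx) - 1L) / factor) + 1L
  by <- floor((seq_len(ny) - 1L) / factor) + 1L
  nx2 <- max(bx); ny2 <- max(by)
  m <- stack_as_matrix(stack)                      # T x P
  grp <- pixel_index(rep(bx, times = ny), rep(by, each = nx), nx2)
  out <- matrix(0, nt, nx2 * ny2)
  cnt <- tabulate(grp, nbins = nx2 * ny2)
  for (g in seq_len(nx2 * ny2)) {
    cols <- which(grp == g)
    out[, g] <- if (length(cols) > 1L) rowMeans(m[, cols, drop = FALSE]) else m[, cols]
  }
  mask2 <- matrix(TRUE, nx2, ny2)
  voltage_stack(matrix_as_stack_data(out, nx2, ny2), dt_ms = stack$dt_ms,
                pitch_mm = stack$pitch_mm * factor, mask = mask2,
                meta = c(stack$meta, list(downsampled_by = factor)))
}

#' Agreement between a candidate activation map and the ground truth
#'
#' Pixel-to-pixel linear regression of candidate on truth over their common
#' defined pixels, plus each map's total activation time (the 5th-to-95th
#' percentile span).
#'
#' @param candidate,truth [scalar_map()]s on the same grid.
#' @return list with `r2`, `slope`, `span_candidate`, `span_truth` (ms),
#'   `n` common pixels.
#' @export
at_map_agreement <- function(candidate, truth) {
  if (!identical(dim(candidate), dim(truth))) stop("maps are not co-registered")
  ok <- !is.na(candidate) & !is.na(truth)
  if (sum(ok) < 10L) stop("fewer than 10 common pixels")
  xc <- unclass(candidate)[ok]; xt <- unclass(truth)[ok]
  vt <- stats::var(xt)
  if (vt == 0) stop("truth map is constant; regression undefined")
  span <- function(v) diff(stats::quantile(v, c(0.05, 0.95), names = FALSE))
  list(r2 = stats::cor(xc, xt)^2,
       slope = stats::cov(xc, xt) / vt,
       span_candidate = span(xc), span_truth = span(xt), n = sum(ok))
}

#' Canned scenarios: paced planar beats, S1S2S3S4 train, focal point source,
#' cross-field-induced spiral reentry
#'
#' Convenience constructors for the standard validation scenarios. The spiral
#' scenario applies a basic planar train followed by a cross-field
#' half-plane stimulus inside the vulnerable window of the last planar beat,
#' producing sustained reentry; coupling intervals are stated in ms.
#'
#' @param nx,ny grid size.
#' @param duration_ms recording length.
#' @param seed RNG seed.
#' @param s1_times_ms planar S1 stimulus times.
#' @param coupling_ms coupling intervals of the short-coupled extra stimuli.
#' @param s2_delay_ms delay of the cross-field stimulus after the last S1.
#' @param x,y focal source location (point scenario).
#' @return a [sim_scenario()].
#' @export
scenario_planar <- function(nx = 60L, ny = 60L, duration_ms = 1200,
                            s1_times_ms = 100, seed = 1L) {
  sim_scenario(nx, ny, duration_ms, seed = seed,
               stimuli = lapply(s1_times_ms, function(tt)
                 list(kind = "planar_edge", side = "xmin", time_ms = tt,
                      width_px = 3L)))
}

#' @rdname scenario_planar
#' @export
scenario_focal <- function(nx = 60L, ny = 60L, duration_ms = 1200,
                           x = 30L, y = 30L, s1_times_ms = 100, seed = 1L) {
  sim_scenario(nx, ny, duration_ms, seed = seed,
               stimuli = lapply(s1_times_ms, function(tt)
                 list(kind = "point", x = x, y = y, radius_px = 2L,
                      time_ms = tt)))
}

#' @rdname scenario_planar
#' @export
scenario_s1s2s3s4 <- function(nx = 60L, ny = 60L, duration_ms = 3400,
                              s1_times_ms = c(100, 600, 1100),
                              coupling_ms = c(450, 430, 420), seed = 1L) {
  times <- c(s1_times_ms, utils::tail(s1_times_ms, 1L) + cumsum(coupling_ms))
  sim_scenario(nx, ny, duration_ms, seed = seed,
               stimuli = lapply(times, function(tt)
                 list(kind = "planar_edge", side = "xmin", time_ms = tt,
                      width_px = 3L)))
}

#' @rdname scenario_planar
#' @param time_scale_ms ms of recording time per model time unit. The spiral
#'   scenario uses 4 ms, which puts the reentrant cycle length (~114 ms),
#'   basal APD (~125 ms at this rate) and conduction velocity (~0.2 m/s at
#'   0.7 mm pitch) in the range reported for ventricular tachyarrhythmia.
#' @export
scenario_spiral <- function(nx = 100L, ny = 100L, duration_ms = 4000,
                            s1_times_ms = 50, s2_delay_ms = 285,
                            time_scale_ms = 4, seed = 1L) {
  stim <- c(lapply(s1_times_ms, function(tt)
    list(kind = "planar_edge", side = "xmin", time_ms = tt, width_px = 3L)),
    list(list(kind = "cross_field", side = "ylow", frac = 0.5,
              time_ms = utils::tail(s1_times_ms, 1L) + s2_delay_ms)))
  sim_scenario(nx, ny, duration_ms, seed = seed, stimuli = stim,
               params = list(time_scale_ms = time_scale_ms))
}
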