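# Fixtures are built in code; nothing binary ships with the package.

# trapezoidal action-potential train: upstroke `rise` ms, plateau, linear
# repolarization `fall` ms, period `period` ms, first upstroke at `t0` ms.
ap_train <- function(n, period = 500, t0 = 100, rise = 5, plateau = 150,
                     fall = 80, amp = 1) {
  s <- numeric(n)
  t <- 0:(n - 1)
  for (st in seq(t0, n - 1, by = period)) {
    s <- s + pmin(1, pmax(0, (t - st) / rise)) *
      pmin(1, pmax(0, 1 - (t - st - rise - plateau) / fall))
  }
  amp * pmax(0, pmin(1, s))
}

# smooth near-sinusoidal "AP" train (fundamental-dominated spectrum)
smooth_train <- function(n, freq_hz = 2, fs = 1000) {
  tt <- (0:(n - 1)) / fs
  0.5 + 0.5 * sin(2 * pi * freq_hz * tt)
}

# planar-wave stack built directly in normalized units: activation sweeps
# along +x at `v_px_per_ms`; each pixel carries an ap_train-shaped beat per
# entry in t0s. Returns a voltage_stack (already "preconditioned"-like).
planar_stack <- function(nx = 12, ny = 10, nt = 600, v_px_per_ms = 0.5,
                         t0s = 100, rise = 5, plateau = 150, fall = 80) {
  arr <- array(0, dim = c(nx, ny, nt))
  for (x in seq_len(nx)) {
    tr <- numeric(nt)
    for (t0 in t0s)
      tr <- tr + ap_train(nt, period = nt + 1, t0 = t0 + (x - 1) / v_px_per_ms,
                          rise = rise, plateau = plateau, fall = fall)
    tr <- pmin(1, tr)
    for (y in seq_len(ny)) arr[x, y, ] <- tr
  }
  voltage_stack(arr, dt_ms = 1, pitch_mm = 0.7)
}

# hand-built activation event table (for labeling/origin/oracle tests)
make_events <- function(df, nx, ny, dt_ms = 1, pitch_mm = 0.7) {
  ev <- data.table::as.data.table(df)
  if (is.null(ev$component)) ev[, component := "primary"]
  if (is.null(ev$vf_star)) ev[, vf_star := 0.2]
  if (is.null(ev$t_frame)) ev[, t_frame := as.integer(round(t_ms / dt_ms)) + 1L]
  if (is.null(ev$window_id)) ev[, window_id := .I]
  ev[, pixel := x + nx * (y - 1L)]
  data.table::setorder(ev, t_ms, y, x)
  data.table::setattr(ev, "dims", c(nx, ny, max(ev$t_frame) + 1L))
  data.table::setattr(ev, "dt_ms", dt_ms)
  data.table::setattr(ev, "pitch_mm", pitch_mm)
  data.table::setattr(ev, "class",
                      c("activation_events", class(ev)))
  ev
}

# brute-force oracle: transitive closure of pairwise space-time connectivity
# (Chebyshev distance <= 1, |dt| <= theta), labels renumbered by first event
# in (t, y, x) scan order. Independent of the package's graph machinery.
oracle_label <- function(events, theta) {
  ev <- as.data.frame(events)
  n <- nrow(ev)
  lab <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (lab[i] != lab[j] &&
          max(abs(ev$x[i] - ev$x[j]), abs(ev$y[i] - ev$y[j])) <= 1 &&
          abs(ev$t_ms[i] - ev$t_ms[j]) <= theta) {
        m <- min(lab[i], lab[j])
        lab[lab == lab[i] | lab == lab[j]] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  ord <- order(ev$t_ms, ev$y, ev$x)
  first <- !duplicated(lab[ord])
  ren <- integer(max(lab))
  ren[lab[ord][first]] <- seq_len(sum(first))
  ren[lab]
}

# cached medium simulations shared between test files (built on first use)
.sim_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (is.null(.sim_cache[[key]])) .sim_cache[[key]] <- force(expr)
  .sim_cache[[key]]
}

small_planar_sim <- function() cached("planar", {
  sc <- scenario_planar(nx = 40, ny = 40, duration_ms = 1200,
                        s1_times_ms = 100, seed = 7)
  simulate_excitable_sheet(sc)
})

small_focal_sim <- function() cached("focal", {
  sc <- scenario_focal(nx = 40, ny = 40, duration_ms = 1200, x = 20, y = 20,
                       s1_times_ms = 100, seed = 7)
  simulate_excitable_sheet(sc)
})
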