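# Derivative thresholding, activation detection, activation matrix, uAT.

test_that("biphasic split follows the valley-depth rule exactly", {
  # designed derivative profile: two rectangular peaks (h1 = 0.2, h2 = 0.1)
  # joined by a valley plateau v; depth = (h2 - v) / h2 exactly, because the
  # central difference of cumsum(d) averages adjacent pairs and plateaus of
  # width >= 2 keep their value.
  biphasic_signal <- function(depth, n = 60) {
    h1 <- 0.2; h2 <- 0.1
    v <- h2 * (1 - depth)
    d <- numeric(n)
    d[15:39] <- v
    d[10:14] <- h1
    d[40:44] <- h2
    cumsum(d)
  }
  for (depth in c(0.75, 0.8, 1)) {          # split at depth >= 75%
    sig <- biphasic_signal(depth)
    ev <- detect_upstroke_activations(sig, c(1L, 60L), 0.01)
    expect_identical(nrow(ev), 2L, label = sprintf("depth %.2f", depth))
    expect_identical(ev$component, c("primary", "secondary"))
    expect_lt(ev$t_ms[1], ev$t_ms[2])       # primary is chronologically first
  }
  for (depth in c(0.5, 0.7, 0.7499)) {      # no split below 75%
    sig <- biphasic_signal(depth)
    ev <- detect_upstroke_activations(sig, c(1L, 60L), 0.01)
    expect_identical(nrow(ev), 1L, label = sprintf("depth %.2f", depth))
  }
  # monotone decision boundary located by bisection
  lo <- 0.5; hi <- 1
  for (i in 1:20) {
    mid <- (lo + hi) / 2
    n <- nrow(detect_upstroke_activations(biphasic_signal(mid), c(1L, 60L), 0.01))
    if (n == 2L) hi <- mid else lo <- mid
  }
  expect_lt(abs(hi - 0.75), 1e-4)
})

test_that("monophasic upstrokes give a single activation at argmax dF/dt", {
  sig <- 1 / (1 + exp(-0.5 * ((0:99) - 50)))         # sigmoid
  ev <- detect_upstroke_activations(sig, c(1L, 100L), 0.001)
  d <- atmapr:::central_diff(sig, 1)
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$t_frame, which.max(d))
  expect_error(detect_upstroke_activations(sig, c(10L, 11L), 0.001), "3 samples")
})

test_that("two ramps separated by a deep valley give two activations", {
  # 3-sample ramps produce strict derivative peaks at the ramp midpoints
  sig <- c(rep(0, 10), 0.25, 0.5, rep(0.5, 20), 0.75, 1, rep(1, 10))
  d <- atmapr:::central_diff(sig, 1)
  ev <- detect_upstroke_activations(sig, c(1L, length(sig)), 0.01)
  expect_identical(nrow(ev), 2L)
  pk <- order(d, decreasing = TRUE)[1:2]
  expect_setequal(ev$t_frame, sort(pk))
})

test_that("auto threshold: clean stacks keep all true windows", {
  st <- planar_stack(nx = 12, ny = 10, nt = 900, t0s = c(120, 550),
                     plateau = 100, fall = 60)
  w <- stack_upstroke_windows(st)
  th <- auto_derivative_threshold(st, w)
  ev <- build_activation_matrix(st, w, th)
  # two disjoint paced beats: event count = 2 x masked-in pixels
  expect_identical(nrow(ev), 2L * 12L * 10L)
  # threshold at or below the weakest true upstroke derivative (filter is >=)
  m <- atmapr:::stack_as_matrix(st)
  min_true <- min(apply(m, 2, function(v) max(atmapr:::central_diff(v, 1))))
  expect_lte(th$value, min_true)
})

test_that("auto threshold controls the pass fraction on pure noise", {
  set.seed(42)
  nx <- 14; ny <- 14; nt <- 2600
  arr <- array(stats::rnorm(nx * ny * nt), dim = c(nx, ny, nt))
  st <- voltage_stack(arr, dt_ms = 1)
  w <- stack_upstroke_windows(st)
  nwin <- sum(vapply(w$intervals_by_pixel, nrow, integer(1)))
  expect_gt(nwin, 1000)
  th <- auto_derivative_threshold(st, w, fdr_q = 0.01)
  m <- atmapr:::stack_as_matrix(st)
  pass <- 0L
  for (px in seq_len(nx * ny)) {
    iv <- w$intervals_by_pixel[[px]]
    if (!nrow(iv)) next
    d <- atmapr:::central_diff(m[, px], 1)
    for (i in seq_len(nrow(iv)))
      if (max(d[iv[i, 1]:iv[i, 2]]) >= th$value) pass <- pass + 1L
  }
  # expected pass fraction <= q; allow binomial slack above q * nwin
  expect_lt(pass / nwin, 0.01 + 3 * sqrt(0.01 / nwin))
})

test_that("auto threshold refuses tiny window sets", {
  st <- planar_stack(nx = 12, ny = 10, nt = 400, t0s = 100)
  w <- stack_upstroke_windows(st)
  w$intervals_by_pixel <- c(w$intervals_by_pixel[1:10],
                            replicate(110, matrix(integer(0), ncol = 2),
                                      simplify = FALSE))
  expect_error(auto_derivative_threshold(st, w), "manual")
})

test_that("planar wave: pAT is affine in distance and matches the oracle", {
  v <- 0.5                                            # px per ms
  st <- planar_stack(nx = 16, ny = 12, nt = 500, v_px_per_ms = v, t0s = 100)
  w <- stack_upstroke_windows(st)
  th <- auto_derivative_threshold(st, w)
  ev <- build_activation_matrix(st, w, th)
  expect_identical(nrow(ev), 16L * 12L)
  fit <- stats::lm(t_ms ~ x, data = ev)
  expect_equal(unname(stats::coef(fit)[2]), 1 / v, tolerance = 0.05)
  imposed <- 100 + (ev$x - 1) / v + 2                  # ramp midpoint ~ +2.5
  expect_lt(max(abs(ev$t_ms - imposed)), 1.01)         # within one frame

  # exhaustive per-window argmax oracle (on the retained window)
  m <- atmapr:::stack_as_matrix(st)
  for (px in c(3L, 50L, 150L)) {
    evp <- ev[ev$pixel == px, ]
    iv <- w$intervals_by_pixel[[px]]
    hit <- which(iv[, 1] <= evp$t_frame & iv[, 2] >= evp$t_frame)
    expect_length(hit, 1L)
    d <- atmapr:::central_diff(m[, px], 1)
    best <- iv[hit, 1] - 1L + which.max(d[iv[hit, 1]:iv[hit, 2]])
    expect_identical(evp$t_frame, best)
  }

  # amplitude invariance: doubling the signal leaves times unchanged
  st2 <- st; st2$data <- st$data * 2
  ev2 <- build_activation_matrix(st2, w, th)
  expect_identical(ev2$t_frame, ev$t_frame)

  # every event derivative is above threshold
  expect_true(all(ev$vf_star > 0))
  expect_true(all(ev$vf_star <= 1))
})

test_that("batch detection equals the per-window reference implementation", {
  # the stack path runs compiled batch detection; it must agree event-for-
  # event with the single-window R implementation on noisy multi-beat data
  set.seed(8)
  st <- planar_stack(nx = 10, ny = 8, nt = 900, t0s = c(120, 550),
                     plateau = 90, fall = 50)
  st$data <- st$data + array(rnorm(length(st$data), sd = 0.02),
                             dim = dim(st$data))
  w <- stack_upstroke_windows(st, guard_ms = 0)
  th <- manual_derivative_threshold(0.02)
  ev <- build_activation_matrix(st, w, th)
  m <- atmapr:::stack_as_matrix(st)
  wid <- 0L
  for (px in seq_len(10 * 8)) {
    iv <- w$intervals_by_pixel[[px]]
    sig <- m[, px]
    dd <- atmapr:::central_diff(sig, 1)
    for (i in seq_len(nrow(iv))) {
      wid <- wid + 1L
      s <- iv[i, 1]; e <- iv[i, 2]
      keep <- atmapr:::ls_slope(sig[s:e], 1) > 0 && max(dd[s:e]) >= th$value
      ref <- if (keep)
        detect_upstroke_activations(sig, c(s, e), th, dt_ms = 1)
      else activation_df()
      got <- ev[ev$window_id == wid, ]
      expect_identical(nrow(got), nrow(ref))
      if (nrow(ref)) {
        expect_identical(got$t_frame, ref$t_frame)
        expect_identical(got$component, ref$component)
        expect_equal(got$vf_star, ref$vf_star)
      }
    }
  }
})

test_that("empty window set yields an empty matrix", {
  st <- planar_stack(nx = 8, ny = 8, nt = 300)
  w <- stack_upstroke_windows(st)
  w$intervals_by_pixel <- replicate(64, matrix(integer(0), ncol = 2),
                                    simplify = FALSE)
  ev <- build_activation_matrix(st, w, manual_derivative_threshold(0.01))
  expect_identical(nrow(ev), 0L)
})

test_that("events densify into a boolean stack in the raw dialect", {
  st <- planar_stack(nx = 8, ny = 6, nt = 400, t0s = 100)
  w <- stack_upstroke_windows(st)
  ev <- build_activation_matrix(st, w, manual_derivative_threshold(0.02))
  dense <- events_to_stack(ev)
  expect_equal(sum(dense$data), nrow(ev))
  expect_true(all(dense$data[cbind(ev$x, ev$y, ev$t_frame)] == 1))
  f <- tempfile(fileext = ".bin")
  write_raw_stack(dense, f, dtype = "uint16")
  back <- read_raw_stack(f)
  expect_equal(back$data, dense$data)
  unlink(c(f, paste0(f, ".json")))
})

test_that("uniform window reproduces pAT for a fully contained beat", {
  st <- planar_stack(nx = 16, ny = 12, nt = 500, t0s = 100)
  w <- stack_upstroke_windows(st)
  th <- auto_derivative_threshold(st, w)
  ev <- build_activation_matrix(st, w, th)
  u <- uniform_window_at(st, 80, 300)
  for (i in seq_len(nrow(ev)))
    expect_equal(u[ev$x[i], ev$y[i]], ev$t_ms[i])
  expect_error(uniform_window_at(st, 200, 200), "empty")
})
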