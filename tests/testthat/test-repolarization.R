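# Repolarization-time detection, APD limit refinement and APD maps.

test_that("rectangular APs repolarize exactly at the falling edge", {
  cfg <- repolarization_config(level_frac = 0.8, apd_min_ms = 50,
                               apd_max_ms = 400)
  for (D in c(120, 250, 340)) {
    sig <- numeric(600)
    sig[101:(100 + D)] <- 1                # AP from 100 ms, duration D
    rt <- detect_repolarization(sig, 100, cfg)
    expect_equal(rt, 100 + D)
    # any level fraction gives the same sharp-edge crossing
    cfg2 <- repolarization_config(level_frac = 0.3, apd_min_ms = 50,
                                  apd_max_ms = 400)
    expect_equal(detect_repolarization(sig, 100, cfg2), 100 + D)
  }
})

test_that("exponential repolarization matches the closed form", {
  tau <- 80; t_peak <- 120
  tt <- 0:799
  sig <- ifelse(tt < 100, 0, ifelse(tt <= t_peak, (tt - 100) / 20,
                                    exp(-(tt - t_peak) / tau)))
  for (lf in c(0.5, 0.8, 0.9)) {
    cfg <- repolarization_config(level_frac = lf, apd_min_ms = 10,
                                 apd_max_ms = 600)
    rt <- detect_repolarization(sig, 100, cfg)
    expect_equal(rt, t_peak + tau * log(1 / (1 - lf)), tolerance = 2 / rt)
  }
})

test_that("min-derivative method tolerates a drifting baseline", {
  tt <- 0:599
  drift <- 0.0005 * tt                     # linearly rising baseline
  sig0 <- ap_train(600, period = 1000, t0 = 100, rise = 5, plateau = 150,
                   fall = 30)
  cfg_amp <- repolarization_config(apd_min_ms = 50, apd_max_ms = 400)
  cfg_der <- repolarization_config(apd_min_ms = 50, apd_max_ms = 400,
                                   method = "min_derivative")
  steepest <- which.min(atmapr:::central_diff(sig0 + drift, 1)) - 1
  rt_der <- detect_repolarization(sig0 + drift, 100, cfg_der)
  expect_lt(abs(rt_der - steepest), 1.01)
  # the amplitude method is biased upward by the drift on a slow tail
  sigsl <- ap_train(600, period = 1000, t0 = 100, rise = 5, plateau = 100,
                    fall = 150)
  rt_amp0 <- detect_repolarization(sigsl, 100, cfg_amp)
  rt_amp1 <- detect_repolarization(sigsl + drift, 100, cfg_amp)
  expect_gt(rt_amp1, rt_amp0)
})

test_that("no crossing in the interval yields the sentinel", {
  sig <- c(rep(0, 100), rep(1, 500))       # never repolarizes
  cfg <- repolarization_config(apd_min_ms = 50, apd_max_ms = 300)
  expect_true(is.na(detect_repolarization(sig, 100, cfg)))
})

test_that("refine_apd_limits narrows within user limits and falls back", {
  cfg <- repolarization_config(apd_min_ms = 80, apd_max_ms = 400)
  lim <- refine_apd_limits(rep(250, 30), cfg)
  expect_true(lim[1] >= 80 && lim[2] <= 400)
  expect_true(lim[1] <= 250 && lim[2] >= 250)
  expect_lt(lim[2] - lim[1], 320)          # narrower than user limits

  set.seed(3)
  lim2 <- refine_apd_limits(runif(500, 200, 300), cfg)
  expect_gt(lim2[1], 80); expect_lt(lim2[2], 400)

  expect_identical(refine_apd_limits(250, cfg), c(80, 400))  # single event
  expect_warning(out <- refine_apd_limits(numeric(0), cfg), "user APD")
  expect_identical(out, c(80, 400))
})

test_that("apd_map subtracts maps and propagates sentinels", {
  at <- scalar_map(matrix(c(0, 10, 20, NA), 2, 2))
  rt <- scalar_map(matrix(c(250, 260, NA, 300), 2, 2))
  apd <- apd_map(at, rt)
  expect_equal(apd[1, 1], 250)
  expect_equal(apd[2, 1], 250)
  expect_true(is.na(apd[1, 2]) && is.na(apd[2, 2]))
})

test_that("front repolarization recovers an imposed APD gradient", {
  # planar wave with plateau duration rising from 200 to 300 ms along y
  nx <- 10; ny <- 12; nt <- 700
  arr <- array(0, dim = c(nx, ny, nt))
  for (x in 1:nx) for (y in 1:ny) {
    plateau <- 200 + (y - 1) * 100 / (ny - 1)
    arr[x, y, ] <- ap_train(nt, period = 1000, t0 = 100 + (x - 1) * 2,
                            rise = 4, plateau = plateau, fall = 10)
  }
  st <- voltage_stack(arr, dt_ms = 1)
  w <- stack_upstroke_windows(st)
  ev <- build_activation_matrix(st, w, manual_derivative_threshold(0.02))
  lb <- label_wavefronts(ev, wavefront_config(30))
  expect_identical(nrow(lb$info), 1L)
  fr <- front_repolarization(st, ev, lb, 1L,
                             repolarization_config(apd_min_ms = 80,
                                                   apd_max_ms = 400))
  # recovered APD gradient within 2 frames of the imposed one
  imposed <- 200 + (seq_len(ny) - 1) * 100 / (ny - 1)
  got <- colMeans(unclass(fr$apd), na.rm = TRUE)
  offset <- mean(got - imposed)            # level-crossing offset is constant
  expect_lt(max(abs(got - imposed - offset)), 2)
  # invariants: AT < RT <= AT + refined max, RT >= AT + refined min
  ok <- !is.na(fr$rt)
  expect_true(all(fr$rt[ok] > fr$at[ok]))
  expect_true(all(fr$rt[ok] - fr$at[ok] >= fr$limits[1]))
  expect_true(all(fr$rt[ok] - fr$at[ok] <= fr$limits[2]))
})

test_that("successive identical beats give identical APD maps", {
  st <- planar_stack(nx = 10, ny = 8, nt = 1200, t0s = c(100, 700),
                     plateau = 150, fall = 40)
  w <- stack_upstroke_windows(st)
  ev <- build_activation_matrix(st, w, manual_derivative_threshold(0.02))
  lb <- label_wavefronts(ev, wavefront_config(30))
  expect_identical(nrow(lb$info), 2L)
  cfg <- repolarization_config(apd_min_ms = 80, apd_max_ms = 400)
  f1 <- front_repolarization(st, ev, lb, 1L, cfg)
  f2 <- front_repolarization(st, ev, lb, 2L, cfg)
  d <- unclass(f2$apd) - unclass(f1$apd)
  expect_lt(max(abs(d), na.rm = TRUE), 1.01)
})
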