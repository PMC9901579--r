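# Excitable-media simulator and optical observation model.

test_that("no stimulus gives an identically resting stack", {
  sc <- sim_scenario(nx = 16, ny = 16, duration_ms = 300, stimuli = list())
  sim <- simulate_excitable_sheet(sc)
  expect_true(all(sim$membrane$data == 0))
  expect_identical(nrow(sim$truth$events), 0L)
})

test_that("scenario validation and CFL guard", {
  expect_error(sim_scenario(stimuli = list(list(kind = "zap", time_ms = 1))),
               "unknown stimulus")
  expect_error(sim_scenario(duration_ms = 100,
                            stimuli = list(list(kind = "point", x = 5, y = 5,
                                                time_ms = 500))),
               "outside")
  sc <- sim_scenario(nx = 16, ny = 16, duration_ms = 100,
                     params = list(D = 2, dt_model = 0.2),
                     stimuli = list(list(kind = "planar_edge", side = "xmin",
                                         time_ms = 1)))
  expect_error(simulate_excitable_sheet(sc), "CFL")
})

test_that("planar wave front travels at constant speed", {
  sim <- small_planar_sim()
  ev <- sim$truth$events
  mid <- ev[ev$y == 20 & ev$x >= 5 & ev$x <= 35, ]
  fit <- stats::lm(t_ms ~ x, data = mid)
  expect_gt(summary(fit)$r.squared, 0.999)
  # speed in the left and right halves agrees within 5%
  fl <- stats::lm(t_ms ~ x, data = mid[mid$x <= 20, ])
  fr <- stats::lm(t_ms ~ x, data = mid[mid$x > 20, ])
  expect_lt(abs(stats::coef(fl)[2] / stats::coef(fr)[2] - 1), 0.05)
})

test_that("simulation and observation are seed-deterministic", {
  sc1 <- scenario_focal(nx = 20, ny = 20, duration_ms = 400, x = 10, y = 10,
                        seed = 5)
  s1 <- simulate_excitable_sheet(sc1)
  s2 <- simulate_excitable_sheet(sc1)
  expect_identical(s1$membrane$data, s2$membrane$data)
  expect_identical(s1$truth$events, s2$truth$events)
  o1 <- emulate_optical_observation(s1$membrane, 1, 15, seed = 9)
  o2 <- emulate_optical_observation(s2$membrane, 1, 15, seed = 9)
  expect_identical(o1$data, o2$data)
  o3 <- emulate_optical_observation(s1$membrane, 1, 15, seed = 10)
  expect_false(identical(o1$data, o3$data))
})

test_that("optical model: identity at zero blur/noise, SNR and blur effects", {
  sim <- small_planar_sim()
  clean <- emulate_optical_observation(sim$membrane, blur_sigma_px = 0,
                                       snr_target = Inf)
  expect_equal(clean$data, 1 - sim$membrane$data)

  # snr_target 13: measured SNR within 10% (the noisiest usable regime)
  noisy <- emulate_optical_observation(sim$membrane, blur_sigma_px = 0,
                                       snr_target = 13, seed = 2)
  qc <- signal_qc(voltage_stack(noisy$data, dt_ms = 1))
  expect_equal(stats::median(qc$snr, na.rm = TRUE), 13, tolerance = 0.1 * 13)

  # blur widens the upstroke: max dF/dt decreases monotonically with sigma
  px_trace <- function(st) st$data[20, 20, ]
  dmax <- vapply(c(0, 0.5, 1, 2, 3), function(sg) {
    ob <- emulate_optical_observation(sim$membrane, blur_sigma_px = sg,
                                      snr_target = Inf)
    max(-atmapr:::central_diff(px_trace(ob), 1))     # depolarization dip rate
  }, numeric(1))
  expect_true(all(diff(dmax) < 0))
})

test_that("at_map_agreement: identity, shift invariance, input checks", {
  z <- matrix(as.numeric(1:100), 10, 10)
  a <- scalar_map(z)
  ag <- at_map_agreement(a, a)
  expect_equal(ag$r2, 1)
  expect_equal(ag$slope, 1)
  ag2 <- at_map_agreement(scalar_map(z + 55), a)
  expect_equal(ag2$r2, 1)
  expect_equal(ag2$slope, 1)
  sparse <- scalar_map(matrix(c(rep(NA, 95), 1:5), 10, 10))
  expect_error(at_map_agreement(sparse, a), "10 common")
})

test_that("raw-binary round trip preserves the stack", {
  sim <- small_focal_sim()
  ob <- emulate_optical_observation(sim$membrane, 1, 20, seed = 3)
  tmp <- tempfile(fileext = ".bin")
  write_raw_stack(ob, tmp)
  back <- read_raw_stack(tmp)
  expect_equal(back$data, ob$data, tolerance = 1e-6)   # float32 round trip
  expect_identical(dim(back$data), dim(ob$data))
  expect_equal(back$dt_ms, ob$dt_ms)
  expect_equal(back$pitch_mm, ob$pitch_mm)
  unlink(c(tmp, paste0(tmp, ".json")))
})

test_that("scenario JSON round trip reproduces the simulation", {
  sc <- scenario_focal(nx = 16, ny = 16, duration_ms = 300, x = 8, y = 8,
                       s1_times_ms = 50, seed = 11)
  f <- tempfile(fileext = ".json")
  write_scenario(sc, f)
  sc2 <- read_scenario(f)
  s1 <- simulate_excitable_sheet(sc)
  s2 <- simulate_excitable_sheet(sc2)
  expect_identical(s1$membrane$data, s2$membrane$data)
  unlink(f)
})

test_that("downsampling emulates coarser pixel pitch", {
  sim <- small_planar_sim()
  ob <- emulate_optical_observation(sim$membrane, 1, Inf)
  d2 <- downsample_stack(ob, 2)
  expect_identical(dim(d2$data)[1:2], c(20L, 20L))
  expect_equal(d2$pitch_mm, ob$pitch_mm * 2)
  d25 <- downsample_stack(ob, 2.5)
  expect_identical(dim(d25$data)[1:2], c(16L, 16L))
})

test_that("noiseless planar end-to-end: pAT recovers eAT within one frame", {
  # realistic conduction-velocity regime (~0.5 m/s at 0.7 mm/px) so that the
  # inter-pixel delay is about one frame; the stimulated strip is masked out
  # the way stimulus electrodes are in experiments
  sc <- sim_scenario(nx = 40, ny = 40, duration_ms = 450, seed = 7,
                     params = list(time_scale_ms = 1.3),
                     stimuli = list(list(kind = "planar_edge", side = "xmin",
                                         time_ms = 60, width_px = 3)))
  sim <- simulate_excitable_sheet(sc)
  raw <- emulate_optical_observation(sim$membrane, blur_sigma_px = 0,
                                     snr_target = Inf)
  mask <- matrix(TRUE, 40, 40); mask[1:4, ] <- FALSE
  res <- suppressWarnings(
    run_pipeline(raw, mask = mask,
                 config = pipeline_config(theta_t_cb = 10, erp_min = 100,
                                          apd_min_ms = 20, apd_max_ms = 200)))
  ev <- res$events
  tru <- sim$truth$events[x > 4]
  m <- merge(as.data.frame(ev[ev$component == "primary", c("x", "y", "t_ms")]),
             as.data.frame(tru[, c("x", "y", "t_ms")]), by = c("x", "y"),
             suffixes = c("_p", "_e"))
  # constant offset allowed (optical AT lags eAT by a fixed morphology shift)
  offs <- stats::median(m$t_ms_p - m$t_ms_e)
  expect_gte(mean(abs(m$t_ms_p - m$t_ms_e - offs) <= 1), 0.99)
  expect_gt(nrow(m), 0.99 * nrow(tru))
})
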