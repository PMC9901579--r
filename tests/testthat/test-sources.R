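# Repetitiveness, origins, dynamic map stacks, conduction fields and
# source classification.

planar_events <- function(nx = 10, ny = 10, t0s = 0, v_ms_per_px = 3) {
  df <- do.call(rbind, lapply(t0s, function(t0) {
    g <- expand.grid(x = 1:nx, y = 1:ny)
    g$t_ms <- t0 + (g$x - 1) * v_ms_per_px
    g
  }))
  make_events(df, nx, ny)
}

test_that("repetitiveness: single beat no, sustained cycles yes", {
  ev1 <- planar_events(t0s = 0)
  lb1 <- label_wavefronts(ev1, wavefront_config(10))
  r1 <- classify_repetitiveness(ev1, lb1, 1L, erp_min_ms = 200)
  expect_identical(r1$classification, "non_repetitive")
  expect_true(all(r1$repetition_map == 0, na.rm = TRUE))  # identically zero

  # rotor-like loop: a wave circulating the perimeter of a 5x5 square
  # (16 pixels, consecutive ones 8-adjacent), 10 ms per step -> period
  # 160 ms, 5 full cycles in one continuously connected label
  per <- rbind(cbind(1:5, 1), cbind(5, 2:5), cbind(4:1, 5), cbind(1, 4:2))
  k <- 5
  df <- do.call(rbind, lapply(0:(k - 1), function(cy)
    data.frame(x = per[, 1], y = per[, 2],
               t_ms = cy * 160 + (seq_len(16) - 1) * 10)))
  evk <- make_events(df, 5, 5)
  lbk <- label_wavefronts(evk, wavefront_config(40))
  expect_identical(nrow(lbk$info), 1L)
  rk <- classify_repetitiveness(evk, lbk, 1L, erp_min_ms = 100)
  expect_identical(rk$classification, "repetitive")
  expect_true(all(rk$repetition_map == k - 1, na.rm = TRUE))

  # re-excitation faster than the ERP is not a repetition
  ev2 <- planar_events(t0s = c(0, 100))
  lb2 <- label_wavefronts(ev2, wavefront_config(150))
  r2 <- classify_repetitiveness(ev2, lb2, 1L, erp_min_ms = 200)
  expect_identical(r2$classification, "non_repetitive")
  expect_true(all(r2$repetition_map == 0, na.rm = TRUE))
})

test_that("ERPmin default is 80% of the minimum basal APD", {
  expect_identical(default_erp_min(250), 200)
})

test_that("origins: interior focal source is a breakthrough at the stimulus", {
  nx <- 21; ny <- 21
  g <- expand.grid(x = 1:nx, y = 1:ny)
  g$t_ms <- 3 * round(sqrt((g$x - 11)^2 + (g$y - 11)^2))   # radial spread
  ev <- make_events(g, nx, ny)
  lb <- label_wavefronts(ev, wavefront_config(15))
  org <- detect_activation_origins(ev, lb, 1L, erp_min_ms = 200,
                                   mask = matrix(TRUE, nx, ny))
  expect_identical(nrow(org$clusters), 1L)
  expect_identical(org$clusters$type, "breakthrough")
  expect_identical(org$clusters$centroid_x, 11L)
  expect_identical(org$clusters$centroid_y, 11L)
})

test_that("origins: planar entry from the left edge is passive", {
  ev <- planar_events(nx = 12, ny = 8)
  lb <- label_wavefronts(ev, wavefront_config(10))
  org <- detect_activation_origins(ev, lb, 1L, erp_min_ms = 200,
                                   mask = matrix(TRUE, 12, 8))
  expect_identical(nrow(org$clusters), 1L)
  expect_identical(org$clusters$type, "passive")
  mem <- org$members
  expect_true(all(mem$x == 1))                      # only the entry edge
})

test_that("origins: simultaneous plateau fed by an earlier source is rejected", {
  # feeder column x = 1 at t = 0, plateau x in 3..8 simultaneously at t = 50,
  # bridge pixel x = 2 at t = 48 links them
  df <- rbind(data.frame(x = 1, y = 1:8, t_ms = 0),
              data.frame(x = 2, y = 1:8, t_ms = 48),
              expand.grid(x = 3:8, y = 1:8) |> transform(t_ms = 50))
  ev <- make_events(df, nx = 8, ny = 8)
  lb <- label_wavefronts(ev, wavefront_config(60))
  org <- detect_activation_origins(ev, lb, 1L, erp_min_ms = 200,
                                   mask = matrix(TRUE, 8, 8))
  # the broad plateau cluster is a false positive; only the true edge
  # source at x = 1 survives
  expect_true(all(org$members$x == 1))
})

test_that("origin recall/precision for multiple separated foci", {
  nx <- 40; ny <- 40
  foci <- list(c(8, 8, 0), c(30, 10, 0), c(15, 32, 0))
  g <- expand.grid(x = 1:nx, y = 1:ny)
  d <- sapply(foci, function(f) 3 * sqrt((g$x - f[1])^2 + (g$y - f[2])^2) + f[3])
  g$t_ms <- round(apply(d, 1, min))
  ev <- make_events(g, nx, ny)
  lb <- label_wavefronts(ev, wavefront_config(15))
  org <- detect_activation_origins(ev, lb, 1L, erp_min_ms = 300,
                                   mask = matrix(TRUE, nx, ny))
  bt <- org$clusters[org$clusters$type == "breakthrough"]
  expect_identical(nrow(bt), 3L)
  for (f in foci) {
    dd <- sqrt((bt$centroid_x - f[1])^2 + (bt$centroid_y - f[2])^2)
    expect_lte(min(dd), 1)
  }
})

test_that("dynamic map stack tiles the episode and conserves events", {
  ev1 <- planar_events(t0s = 0)
  d1 <- dynamic_map_stack(ev1)
  expect_identical(length(d1$maps), 1L)              # single beat: one map
  expect_equal(unclass(d1$maps[[1]])[5, 5], 12)

  evk <- planar_events(t0s = c(0, 300, 600))
  dk <- dynamic_map_stack(evk)
  expect_identical(length(dk$maps), 3L)
  # conservation: every event appears exactly once as a fresh write
  expect_identical(length(dk$map_index), nrow(evk))
  expect_equal(sum(dk$spans$n_fresh), nrow(evk))
  # within each map the fresh span is at most one beat interval
  expect_true(all(dk$spans$t_last_ms - dk$spans$t_first_ms < 300))
  # multiset of mapped times equals multiset of event times
  expect_identical(sort(dk$events$t_ms), sort(evk$t_ms))
})

test_that("conduction vectors: planar ramp, radial focus, flat patch", {
  ramp <- scalar_map(matrix(rep(1:12, 10) * 2, 12, 10), pitch_mm = 1)
  v <- conduction_vector_field(ramp)
  expect_true(all(abs(v$ux - 1) < 1e-9, na.rm = TRUE))
  expect_true(all(abs(v$uy) < 1e-9, na.rm = TRUE))

  g <- expand.grid(x = 1:21, y = 1:21)
  cone <- matrix(3 * sqrt((g$x - 11)^2 + (g$y - 11)^2), 21, 21)
  vc <- conduction_vector_field(scalar_map(cone, pitch_mm = 1))
  for (p in list(c(11, 4), c(17, 11), c(15, 15))) {
    x <- p[1]; y <- p[2]
    r <- c(x - 11, y - 11) / sqrt(sum((c(x, y) - 11)^2))
    ang <- acos(sum(r * c(vc$ux[x, y], vc$uy[x, y])))
    expect_lt(ang * 180 / pi, 5)                     # radial within 5 degrees
  }

  flat <- scalar_map(matrix(7, 9, 9))
  vf <- conduction_vector_field(flat)
  expect_true(all(is.na(vf$ux)))                     # zero gradient undefined
})

test_that("conduction fields: planar corridor, isolated leading point", {
  ramp <- scalar_map(matrix(rep(1:12, 8) * 4, 12, 8), pitch_mm = 1)
  v <- conduction_vector_field(ramp)
  flds <- leading_front_conduction_fields(ramp, v, theta_t_cb_ms = 10)
  # leading points are the last column
  leads <- do.call(rbind, lapply(flds, function(f) f$leading))
  expect_true(all(leads[, 1] == 12))
  expect_identical(nrow(leads), 8L)
  # the field walks back the corridor (theta 10 ms / 4 ms per px -> reaches
  # neighbors at most 2 columns back each hop, chaining to the entry edge)
  f1 <- flds[[1]]$points
  expect_gte(max(12 - f1$x), 10)

  # a lone defined pixel is its own field
  lone <- scalar_map(matrix(c(NA, NA, NA, 5, rep(NA, 5)), 3, 3))
  vl <- conduction_vector_field(lone)
  fl <- leading_front_conduction_fields(lone, vl, 10)
  expect_identical(length(fl), 1L)
  expect_identical(nrow(fl[[1]]$points), 1L)
})

test_that("source classification covers the five classes", {
  # planar wave entering at x = 1: passive drive
  ev <- planar_events(nx = 12, ny = 8, v_ms_per_px = 4)
  lb <- label_wavefronts(ev, wavefront_config(10))
  org <- detect_activation_origins(ev, lb, 1L, 200, matrix(TRUE, 12, 8))
  dm <- dynamic_map_stack(ev)
  mp <- dm$maps[[1]]
  v <- conduction_vector_field(mp)
  flds <- leading_front_conduction_fields(mp, v, 10)
  cl <- classify_front_sources(flds, org, erp_min_ms = 200,
                               theta_t_cb_ms = 10)
  expect_gt(cl$counts[["passive"]], 0)
  expect_identical(cl$counts[["breakthrough"]], 0)
  expect_equal(sum(cl$percentages, na.rm = TRUE), 100, tolerance = 1e-6)

  # focal source: breakthrough drive
  nx <- 21; ny <- 21
  g <- expand.grid(x = 1:nx, y = 1:ny)
  g$t_ms <- 4 * round(sqrt((g$x - 11)^2 + (g$y - 11)^2))
  evf <- make_events(g, nx, ny)
  lbf <- label_wavefronts(evf, wavefront_config(15))
  orgf <- detect_activation_origins(evf, lbf, 1L, 200, matrix(TRUE, nx, ny))
  dmf <- dynamic_map_stack(evf)
  vf <- conduction_vector_field(dmf$maps[[1]])
  fldsf <- leading_front_conduction_fields(dmf$maps[[1]], vf, 15)
  clf <- classify_front_sources(fldsf, orgf, 200, 15)
  expect_gt(clf$counts[["breakthrough"]], 0)

  # classification is invariant to time-origin shifts
  evs <- data.table::copy(evf); evs[, t_ms := t_ms + 1000]
  evs <- make_events(as.data.frame(evs[, list(x, y, t_ms)]), nx, ny)
  lbs <- label_wavefronts(evs, wavefront_config(15))
  orgs <- detect_activation_origins(evs, lbs, 1L, 200, matrix(TRUE, nx, ny))
  dms <- dynamic_map_stack(evs)
  vs <- conduction_vector_field(dms$maps[[1]])
  fldss <- leading_front_conduction_fields(dms$maps[[1]], vs, 15)
  cls <- classify_front_sources(fldss, orgs, 200, 15)
  expect_identical(cls$counts, clf$counts)
})

test_that("classification JSON and dynamic-stack series exports", {
  ev <- planar_events(nx = 10, ny = 8, v_ms_per_px = 4)
  lb <- label_wavefronts(ev, wavefront_config(10))
  org <- detect_activation_origins(ev, lb, 1L, 200, matrix(TRUE, 10, 8))
  dm <- dynamic_map_stack(ev)
  v <- conduction_vector_field(dm$maps[[1]])
  flds <- leading_front_conduction_fields(dm$maps[[1]], v, 10)
  cl <- classify_front_sources(flds, org, 200, 10)
  f <- tempfile(fileext = ".json")
  write_classification_json(cl, f)
  back <- jsonlite::fromJSON(f)
  expect_equal(back$counts$passive, unname(cl$counts["passive"]))
  expect_equal(sum(unlist(back$percentages)), 100, tolerance = 1e-6)
  unlink(f)

  dir <- withr::local_tempdir()
  write_dynamic_stack(dm, file.path(dir, "at"))
  expect_identical(length(list.files(dir, pattern = "^at_\\d+\\.csv$")),
                   length(dm$maps))
})

test_that("two independent fronts give disjoint conduction fields", {
  # two ramps on separate halves advancing in opposite directions
  z <- matrix(NA_real_, 13, 9)
  z[1:5, ] <- matrix(rep(1:5, 9) * 4, 5, 9)
  z[9:13, ] <- matrix(rep(5:1, 9) * 4, 5, 9)
  mp <- scalar_map(z, pitch_mm = 1)
  v <- conduction_vector_field(mp)
  flds <- leading_front_conduction_fields(mp, v, 10)
  keys <- lapply(flds, function(f) paste(f$points$x, f$points$y))
  left <- unlist(keys[vapply(flds, function(f) f$leading[1] <= 5, logical(1))])
  right <- unlist(keys[vapply(flds, function(f) f$leading[1] >= 9, logical(1))])
  expect_length(intersect(left, right), 0L)
})
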