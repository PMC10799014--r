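wound_fixture <- function(v = 10, n_frames = 21, seed = 4, frame_size = 300,
                          pixel_size = 2, initial_width = 500) {
  generate_wound_series(
    wound_spec(frame_size = frame_size, pixel_size = pixel_size,
               initial_width = initial_width, edge_velocity = v, dt = 1,
               n_frames = n_frames, seed = seed))
}

test_that("a single frame is segmented to the true width and area", {
  gw <- wound_fixture()
  truth <- gw$truth$frames
  k <- 11  # true width 300 um
  wf <- segment_wound(gw$frames[[k]], pixel_size = 2)
  expect_lte(abs(wf$width_um - truth$width_um[k]), 5)
  expect_lte(abs(wf$area_um2 - truth$area_um2[k]) / truth$area_um2[k], 0.03)
})

test_that("a confluent frame reports a closed wound", {
  set.seed(9)
  conf <- matrix(100 + rnorm(300 * 300, 0, 12), 300, 300)
  expect_warning(wf <- segment_wound(conf))
  expect_equal(wf$area_um2, 0)
  expect_equal(wf$width_um, 0)
})

test_that("texture segmentation is invariant to global intensity scaling", {
  gw <- wound_fixture(n_frames = 6)
  fr <- gw$frames[[5]]
  expect_identical(segment_wound(fr)$mask, segment_wound(fr * 2)$mask)
})

test_that("fluorescence-threshold mode segments a live-stain frame", {
  gw <- wound_fixture(n_frames = 3)
  wf <- segment_wound(gw$frames[[1]], mode = "fluorescence_threshold",
                      pixel_size = 2)
  expect_lte(abs(wf$width_um - 500) / 500, 0.02)
})

test_that("the closure equation reproduces its defining cases", {
  expect_equal(closure_pct(100, 25), 75)
  expect_equal(closure_pct(100, 100), 0)
  expect_equal(closure_pct(100, 0), 100)
  expect_equal(closure_pct(100, 120), -20)  # growing wound reported as-is
  expect_error(closure_pct(0, 10), "positive")
})

test_that("the migration-rate equation reproduces its defining cases", {
  expect_equal(migration_rate(500, 100, 20), 20)
  expect_equal(migration_rate(300, 300, 8), 0)
  expect_error(migration_rate(500, 100, 0), "positive")
})

test_that("closure is invariant to uniform spatial rescaling", {
  areas <- c(4e5, 3e5, 1e5)
  expect_equal(closure_pct(areas[1], areas), closure_pct(areas[1] * 4, areas * 4))
})

test_that("measured kinetics recover the generator's front velocity", {
  gw <- wound_fixture(v = 10)
  ms <- measure_wound_series(gw$frames, dt = 1, pixel_size = 2)
  truth <- gw$truth$frames
  # per-frame width within 2% of truth
  expect_true(all(abs(ms$width_um - truth$width_um) / truth$width_um <= 0.02))
  wk <- wound_kinetics(ms)
  expect_lte(abs(wk$migration_rate_um_h - 20) / 20, 0.05)
  clo_true <- closure_pct(truth$area_um2[1], truth$area_um2)
  expect_true(all(abs(wk$curve$closure_pct - clo_true) <= 3))
  expect_equal(wk$curve$closure_pct[1], 0)
})

test_that("migration rate equals the least-squares slope for linear series", {
  series <- tibble::tibble(frame = 1:6, t = 0:5,
                           width_um = 400 - 30 * (0:5),
                           area_um2 = (400 - 30 * (0:5)) * 600,
                           width_sd_um = 0)
  wk <- wound_kinetics(series)
  slope <- unname(coef(lm(width_um ~ t, series))[2])
  expect_equal(wk$migration_rate_um_h, -slope)
})

test_that("early closure stops the clock at the first closed frame", {
  series <- tibble::tibble(frame = 1:5, t = 0:4,
                           width_um = c(100, 50, 0, 0, 0),
                           area_um2 = c(100, 50, 0, 0, 0) * 300,
                           width_sd_um = 0)
  wk <- wound_kinetics(series)
  expect_equal(wk$t_span_h, 2)
  expect_equal(wk$migration_rate_um_h, 50)
  expect_true(wk$closed)
  expect_error(wound_kinetics(series[1, ]))
})

test_that("kinetics summaries surface through glance and tidy", {
  gw <- wound_fixture(n_frames = 6)
  wk <- wound_kinetics(measure_wound_series(gw$frames, dt = 1, pixel_size = 2))
  gl <- glance(wk)
  expect_equal(gl$n_frames, 6)
  expect_named(tidy(wk),
               c("frame", "t", "area_um2", "width_um", "width_sd_um",
                 "closure_pct"))
})
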