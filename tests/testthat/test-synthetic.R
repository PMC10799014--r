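test_that("ground truth lists exactly the objects the spec declares", {
  fibres <- lapply(1:5, function(i) {
    fibre_spec(c(40 + 30 * i, 100 + 10 * i), length = 40, width = 3,
               orientation = 20 * i - 50)
  })
  spec <- cell_spec("crossbow", image_size = 256, fibres = fibres,
                    n_nuclei = 1, noise_sd = 0, seed = 7)
  g <- generate_micropattern_cell(spec)
  expect_equal(nrow(g$truth$fibres), 5)
  expect_equal(sum(grepl("^fibre_", names(g$truth$masks))), 5)
  expect_equal(nrow(g$truth$nuclei), 1)
  expect_equal(g$truth$summaries$n_fibres, 5)
  expect_equal(g$truth$summaries$n_nuclei, 1)
})

test_that("noiseless rendering stays inside the declared masks", {
  g <- single_fibre_cell(50, 3, 0, noise_sd = 0, seed = 2, centre_jitter = 0)
  above <- which(g$channels$actin > 10)
  expect_true(all(above %in% g$truth$masks$fibre_1))
  expect_gt(length(above), 0)
})

test_that("the same spec and seed give bit-identical images", {
  s <- cell_spec("crossbow", image_size = 128, n_nuclei = 1, noise_sd = 5,
                 seed = 33)
  expect_identical(generate_micropattern_cell(s)$channels,
                   generate_micropattern_cell(s)$channels)
  expect_identical(generate_foci_image(50, seed = 8)$truth$foci,
                   generate_foci_image(50, seed = 8)$truth$foci)
  w <- wound_spec(frame_size = 128, n_frames = 3, seed = 4)
  expect_identical(generate_wound_series(w)$frames,
                   generate_wound_series(w)$frames)
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(generate_foci_image(5, seed = 123))
  expect_identical(runif(1), before)
})

test_that("foci images honour count, separation and the blank case", {
  blank <- generate_foci_image(0, seed = 1)
  expect_equal(nrow(blank$truth$foci), 0)
  expect_true(all(blank$image <= 10 + 5 * 2))

  g <- generate_foci_image(12, noise_sd = 0, seed = 3)
  lab <- EBImage::bwlabel((g$image > 10) * 1)
  expect_equal(max(as.integer(lab)), 12)

  g50 <- generate_foci_image(50, min_separation = 12, seed = 5)
  d <- as.matrix(dist(cbind(g50$truth$foci$x, g50$truth$foci$y)))
  diag(d) <- Inf
  expect_gte(min(d), 12)
})

test_that("impossible placements are rejected with a placement error", {
  expect_error(
    generate_micropattern_cell(
      cell_spec("none", image_size = 64,
                fibres = list(fibre_spec(c(60, 32), 40, 3, 0)),
                n_nuclei = 0, seed = 1)),
    "placement error")
  expect_error(generate_foci_image(500, min_separation = 30,
                                   image_size = 128, seed = 1),
               "placement error")
})

test_that("wound truth follows the closing-front arithmetic", {
  static <- generate_wound_series(
    wound_spec(frame_size = 64, edge_velocity = 0, n_frames = 5,
               initial_width = 60, pixel_size = 1, seed = 2))
  expect_true(all(static$truth$frames$width_um == 60))

  w <- generate_wound_series(
    wound_spec(frame_size = 64, pixel_size = 16, initial_width = 500,
               edge_velocity = 10, dt = 1, n_frames = 12, seed = 3))
  # frame index k counts from 0: width at k = 10 is 500 - 2*10*10
  expect_equal(w$truth$frames$width_um[11], 300)

  long <- generate_wound_series(
    wound_spec(frame_size = 64, pixel_size = 16, initial_width = 100,
               edge_velocity = 10, dt = 1, n_frames = 10, seed = 4))
  expect_true(all(diff(long$truth$frames$width_um) <= 0))
  expect_true(all(long$truth$frames$width_um[6:10] == 0))
})

test_that("noise level does not alter any ground-truth field", {
  mk <- function(noise) {
    spec <- cell_spec("none", image_size = 128,
                      fibres = list(fibre_spec(c(64, 64), 40, 3, 15)),
                      n_nuclei = 0, noise_sd = noise, seed = 11)
    t <- generate_micropattern_cell(spec)$truth
    t$spec$noise_sd <- NULL
    t
  }
  expect_identical(mk(0)$fibres, mk(8)$fibres)
  expect_identical(mk(0)$masks, mk(8)$masks)
})

test_that("noiseless images are reconstructible from truth masks + background", {
  g <- single_fibre_cell(50, 3, 0, noise_sd = 0, seed = 2, centre_jitter = 0)
  img <- g$channels$actin
  outside <- setdiff(seq_along(img), g$truth$masks$fibre_1)
  expect_true(all(img[outside] == 10))
})
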