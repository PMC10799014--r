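test_that("a single noiseless horizontal fibre is measured to spec", {
  g <- single_fibre_cell(50, 3, 0, noise_sd = 0, seed = 2, centre_jitter = 0)
  fs <- detect_filaments(g$channels$actin, min_length = 10)
  expect_equal(nrow(fs), 1)
  expect_lte(abs(fs$length_px - 50), 2)
  expect_lte(abs(fs$width_px - 3), 0.5)
  expect_lte(angle_diff(fs$orientation_deg, 0), 2)
  expect_true(fs$x >= min(fs$trace[[1]][, 1]) & fs$x <= max(fs$trace[[1]][, 1]))
})

test_that("a blank image yields an empty filament set", {
  fs <- suppressWarnings(detect_filaments(matrix(10, 64, 64)))
  expect_s3_class(fs, "filament_set")
  expect_equal(nrow(fs), 0)
})

test_that("two parallel disjoint fibres give two records with equal orientation", {
  spec <- cell_spec("none", image_size = 128,
                    fibres = list(fibre_spec(c(64, 44), 60, 3, 10),
                                  fibre_spec(c(64, 84), 60, 3, 10)),
                    n_nuclei = 0, noise_sd = 2, seed = 6)
  g <- generate_micropattern_cell(spec)
  fs <- detect_filaments(g$channels$actin)
  expect_equal(nrow(fs), 2)
  expect_lte(angle_diff(fs$orientation_deg[1], fs$orientation_deg[2]), 2)
})

test_that("filament count matches truth on noiseless non-overlapping fixtures", {
  spec <- cell_spec("none", image_size = 200,
                    fibres = list(fibre_spec(c(50, 50), 60, 3, 0),
                                  fibre_spec(c(140, 60), 50, 4, 80),
                                  fibre_spec(c(100, 150), 70, 5, -40)),
                    n_nuclei = 0, noise_sd = 0, seed = 8)
  g <- generate_micropattern_cell(spec)
  fs <- detect_filaments(g$channels$actin)
  expect_equal(nrow(fs), 3)
})

test_that("recovery errors stay within the measurement envelope", {
  res <- run_fibre_sweep(fibre_sweep_params(40, seed = 900))
  expect_true(all(res$n_detected == 1))
  expect_lte(median(abs(res$est_length - res$true_length) / res$true_length), 0.05)
  expect_lte(median(abs(res$est_width - res$true_width) / res$true_width), 0.15)
  expect_lte(median(angle_diff(res$est_orientation, res$true_orientation)), 3)
})

test_that("physical units scale linearly with pixel size", {
  g <- single_fibre_cell(50, 3, 0, noise_sd = 0, seed = 2, centre_jitter = 0)
  f1 <- detect_filaments(g$channels$actin, pixel_size = 1)
  f2 <- detect_filaments(g$channels$actin, pixel_size = 0.25)
  expect_equal(f2$length_um, f1$length_um * 0.25)
  expect_equal(f2$width_um, f1$width_um * 0.25)
})

test_that("the thick-object gate is strictly greater-than", {
  recs <- tibble::tibble(x = 1:3, y = 1:3, width_px = c(1, 2, 3),
                         width_um = c(1, 2, 3))
  kept <- thick_object_map(recs, width_threshold = 2)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$width_px, 3)
  expect_equal(nrow(thick_object_map(recs[0, ], 2)), 0)
  expect_equal(nrow(thick_object_map(recs, 0.5)), 3)
})

test_that("edge distances agree with a brute-force arc oracle", {
  geo <- crossbow_pattern(256)$geometry
  th <- seq(geo$theta_start, geo$theta_end, length.out = 20000)
  arc <- cbind(geo$centre[1] + geo$radius * cos(th * pi / 180),
               geo$centre[2] - geo$radius * sin(th * pi / 180))
  set.seed(3)
  pts <- tibble::tibble(x = runif(40, 1, 256), y = runif(40, 1, 256))
  out <- edge_distance(pts, geo, pixel_size = 1)
  oracle <- vapply(seq_len(40), function(i) {
    min(sqrt((arc[, 1] - pts$x[i])^2 + (arc[, 2] - pts$y[i])^2))
  }, numeric(1))
  expect_lt(max(abs(out$edge_distance_px - oracle)), 0.5)

  on_arc <- tibble::tibble(x = arc[5000, 1], y = arc[5000, 2])
  expect_lt(edge_distance(on_arc, geo)$edge_distance_px, 1e-6)
  centre <- tibble::tibble(x = geo$centre[1], y = geo$centre[2])
  expect_equal(edge_distance(centre, geo)$edge_distance_px, geo$radius)
})

test_that("skeleton stats match the simple-path and crossing fixtures", {
  n <- 64
  line <- matrix(FALSE, n, n)
  line[10:54, 32] <- TRUE
  expect_equal(skeleton_stats(line),
               tibble::tibble(n_branches = 1L, n_junctions = 0L))
  expect_equal(skeleton_stats(x_mask()),
               tibble::tibble(n_branches = 4L, n_junctions = 1L))
  empty <- skeleton_stats(matrix(FALSE, 16, 16))
  expect_equal(empty$n_branches, 0L)
  expect_equal(empty$n_junctions, 0L)
})

test_that("orientation histogram localises fibre direction", {
  mk <- function(ori) {
    generate_micropattern_cell(
      cell_spec("none", image_size = 128,
                fibres = list(fibre_spec(c(64, 64), 60, 4, ori)),
                n_nuclei = 0, noise_sd = 2, seed = 3))$channels$actin
  }
  oh0 <- orientation_distribution(mk(0))
  modal <- oh0$hist[which.max(oh0$hist$weight), ]
  expect_true(modal$bin_left <= 0 && 0 <= modal$bin_right)
  oh45 <- orientation_distribution(mk(45))
  modal45 <- oh45$hist[which.max(oh45$hist$weight), ]
  bw <- modal45$bin_right - modal45$bin_left
  expect_lte(abs(45 - modal45$bin_mid), bw)
  expect_gt(oh0$coherence, 0.5)
})

test_that("orientation histogram is equivariant under 90-degree rotation", {
  img <- generate_micropattern_cell(
    cell_spec("none", image_size = 128,
              fibres = list(fibre_spec(c(64, 64), 60, 4, 30)),
              n_nuclei = 0, noise_sd = 2, seed = 3))$channels$actin
  rot <- t(img)[, nrow(img):1]
  m1 <- orientation_distribution(img)$mean_deg
  m2 <- orientation_distribution(rot)$mean_deg
  expect_lte(angle_diff(m1 - 90, m2), 2)
})

test_that("isotropic noise has near-zero coherence and constant images warn", {
  set.seed(42)
  noise <- matrix(rnorm(128 * 128, 50, 10), 128, 128)
  expect_lt(orientation_distribution(noise)$coherence, 0.1)
  expect_warning(oh <- orientation_distribution(matrix(3, 32, 32)), "constant")
  expect_equal(sum(oh$hist$weight), 0)
})
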