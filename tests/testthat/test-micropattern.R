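test_that("automatic thresholds separate a two-level image exactly", {
  im <- matrix(10, 64, 64)
  im[20:40, 20:40] <- 200
  for (m in c("huang", "max_entropy", "median", "otsu")) {
    pp <- preprocess(im, gaussian_sigma = 0, threshold_method = m)
    expect_identical(pp$mask, im == 200)
  }
})

test_that("a constant image yields an empty mask with a warning", {
  expect_warning(pp <- preprocess(matrix(5, 32, 32)), "constant")
  expect_false(any(pp$mask))
  expect_true(is.na(pp$threshold))
})

test_that("the preprocessing mask covers the true object masks on noiseless cells", {
  spec <- cell_spec("crossbow", image_size = 128,
                    fibres = list(fibre_spec(c(64, 80), 40, 4, 10)),
                    n_nuclei = 1, nucleus_radius = 10, noise_sd = 0, seed = 3)
  g <- generate_micropattern_cell(spec)
  pp <- preprocess(g$channels$actin, gaussian_sigma = 0,
                   threshold_method = "median")
  support <- g$truth$masks$fibre_1
  expect_gte(mean(pp$mask[support]), 0.99)
  pp_h <- preprocess(g$channels$actin, gaussian_sigma = 1,
                     threshold_method = "huang")
  expect_gte(mean(pp_h$mask[g$truth$core_masks$fibre_1]), 0.99)
})

test_that("QC classifies nucleus counts per the exclusion rules", {
  expect_equal(qc_cell(qc_fixture(2, seed = 7)$channels$dapi),
               "excluded_multinucleate")
  expect_equal(qc_cell(qc_fixture(1, seed = 6)$channels$dapi), "passed")
  expect_equal(qc_cell(qc_fixture(0, seed = 5)$channels$dapi),
               "excluded_offpattern")
})

test_that("QC never passes a multinucleate fixture (no false accepts)", {
  status <- vapply(1:8, function(s) {
    qc_cell(qc_fixture(2, seed = 40 + s)$channels$dapi)
  }, character(1))
  expect_true(all(status == "excluded_multinucleate"))
})

test_that("a small condensed nucleus is flagged mitotic against a cohort reference", {
  spec <- cell_spec("crossbow", image_size = 128, n_nuclei = 1,
                    nucleus_radius = 6, noise_sd = 2, seed = 9)
  small <- generate_micropattern_cell(spec)$channels$dapi
  ref_area <- pi * 12^2
  expect_equal(qc_cell(small, area_ref = ref_area, solidity_max = 0.8),
               "excluded_mitotic")
  expect_equal(qc_cell(small, area_ref = NULL), "passed")
})

test_that("centring recovers a known shift and is idempotent", {
  g <- generate_micropattern_cell(
    cell_spec("crossbow", image_size = 128, n_nuclei = 1,
              nucleus_radius = 10, noise_sd = 3, seed = 9))
  cs <- cell_image_set(g$channels, cell_id = "c1")
  cs$channels <- lapply(cs$channels, actinmorph:::shift_image,
                        dx = 7, dy = -4, fill = 10)
  tmpl <- crossbow_pattern(128)$mask
  centred <- center_on_pattern(cs, tmpl)
  expect_lte(max(abs(centred$centring_offset - c(-7, 4))), 1)
  again <- center_on_pattern(centred, tmpl)
  expect_lte(max(abs(again$centring_offset - centred$centring_offset)), 1)
})

test_that("a blank pattern channel is excluded as off pattern", {
  blank <- cell_image_set(list(pattern = matrix(10, 128, 128)))
  tmpl <- crossbow_pattern(128)$mask
  expect_warning(out <- center_on_pattern(blank, tmpl))
  expect_equal(out$qc_status, "excluded_offpattern")
})

test_that("stack registration recovers translations", {
  g <- generate_micropattern_cell(
    cell_spec("crossbow", image_size = 128, n_nuclei = 1, noise_sd = 3,
              seed = 21))
  base <- g$channels$actin
  one <- register_stack(list(base))
  expect_equal(unlist(one$shifts[1, c("dx", "dy")]), c(dx = 0, dy = 0))

  shifted <- actinmorph:::shift_image(base, 5, -3, fill = 10)
  set.seed(1)
  noisy <- shifted + matrix(rnorm(length(base), 0, 2), nrow(base))
  rs <- register_stack(list(base, shifted, noisy))
  expect_equal(unlist(rs$shifts[2, c("dx", "dy")]), c(dx = -5, dy = 3))
  expect_lte(max(abs(unlist(rs$shifts[3, c("dx", "dy")]) - c(-5, 3))), 1)
})

test_that("frequency map of identical inputs equals the rescaled input", {
  g <- generate_micropattern_cell(
    cell_spec("crossbow", image_size = 96, n_nuclei = 1, noise_sd = 4,
              seed = 12))
  cells <- lapply(1:4, function(i) {
    cell_image_set(g$channels, cell_id = paste0("c", i), qc_status = "passed")
  })
  fm <- build_frequency_map(cells, "actin")
  r <- g$channels$actin
  expected <- matrix(as.integer(round((r - min(r)) / diff(range(r)) * 255)),
                     nrow(r), ncol(r))
  expect_identical(fm$map, expected)
  expect_equal(fm$n_cells, 4)
  expect_equal(range(fm$map), c(0L, 255L))
  # bit-identical on re-run
  expect_identical(build_frequency_map(cells, "actin")$map, fm$map)
})

test_that("frequency map commutes with a mirror flip of all inputs", {
  g <- generate_micropattern_cell(
    cell_spec("crossbow", image_size = 96, n_nuclei = 1, noise_sd = 4,
              seed = 13))
  a <- g$channels$actin
  flip <- function(m) m[nrow(m):1, ]
  cells <- function(imgs) lapply(imgs, function(m) {
    cell_image_set(list(actin = m), qc_status = "passed")
  })
  f1 <- build_frequency_map(cells(list(a, flip(a))), "actin")
  expect_identical(f1$map, flip(f1$map))
})

test_that("a shared fibre locus dominates the cohort frequency map", {
  shared <- fibre_spec(c(64, 40), 50, 4, 0, peak_intensity = 190)
  cells <- lapply(1:12, function(i) {
    set.seed(500 + i)
    distract <- fibre_spec(c(runif(1, 30, 98), runif(1, 70, 110)),
                           30, 3, runif(1, -90, 90), peak_intensity = 150)
    g <- generate_micropattern_cell(
      cell_spec("none", image_size = 128, fibres = list(shared, distract),
                n_nuclei = 0, noise_sd = 4, seed = 500 + i))
    cell_image_set(g$channels, qc_status = "passed")
  })
  fm <- build_frequency_map(cells, "actin")
  peak <- arrayInd(which.max(fm$map), dim(fm$map))
  expect_lte(abs(peak[2] - 40), 3)
  expect_gte(peak[1], 39)
  expect_lte(peak[1], 89)
})

test_that("aggregation rejects bad input", {
  g <- generate_micropattern_cell(cell_spec("crossbow", image_size = 64))
  ok <- cell_image_set(g$channels, qc_status = "passed")
  bad <- cell_image_set(g$channels, qc_status = "excluded_multinucleate")
  expect_error(build_frequency_map(list(), "actin"))
  expect_error(build_frequency_map(list(ok, bad), "actin"), "passed")
  small <- cell_image_set(list(actin = matrix(0, 32, 32)),
                          qc_status = "passed")
  expect_error(build_frequency_map(list(ok, small), "actin"), "dimensions")
})
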