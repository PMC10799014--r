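# Fixture builders shared across the test files. Everything is generated in
# code at run time; seeds are fixed so the suite is deterministic.

# One image containing a single fibre with known parameters.
single_fibre_cell <- function(length, width, orientation, noise_sd = 5,
                              seed = 1, image_size = 256,
                              centre_jitter = 5) {
  ctr <- c(image_size / 2, image_size / 2)
  if (centre_jitter > 0) {
    set.seed(seed)
    ctr <- ctr + runif(2, -centre_jitter, centre_jitter)
  }
  spec <- cell_spec("none", image_size = image_size,
                    fibres = list(fibre_spec(ctr, length, width, orientation)),
                    n_nuclei = 0, noise_sd = noise_sd, seed = seed)
  generate_micropattern_cell(spec)
}

# Random fibre parameter draws spanning the full measurement envelope.
fibre_sweep_params <- function(n, seed = 100) {
  set.seed(seed)
  tibble::tibble(
    length = runif(n, 20, 200),
    width = runif(n, 2, 8),
    orientation = runif(n, -90, 90),
    seed = seed + seq_len(n)
  )
}

# Run the detector over a sweep and return true vs measured values.
run_fibre_sweep <- function(params) {
  purrr::pmap_dfr(params, function(length, width, orientation, seed) {
    g <- single_fibre_cell(length, width, orientation, seed = seed)
    fs <- detect_filaments(g$channels$actin, min_length = 10)
    tibble::tibble(
      true_length = length, true_width = width, true_orientation = orientation,
      n_detected = nrow(fs),
      est_length = if (nrow(fs) == 1) fs$length_px else NA_real_,
      est_width = if (nrow(fs) == 1) fs$width_px else NA_real_,
      est_orientation = if (nrow(fs) == 1) fs$orientation_deg else NA_real_
    )
  })
}

angle_diff <- function(a, b) {
  abs((a - b + 90) %% 180 - 90)
}

# An "X" of two crossing straight lines on an odd-sized grid, so the lines
# share the central pixel.
x_mask <- function(n = 65, from = 11, to = 55) {
  m <- matrix(FALSE, n, n)
  for (i in from:to) {
    m[i, i] <- TRUE
    m[i, n + 1 - i] <- TRUE
  }
  m
}

# A micropatterned cell fixture with nuclei, fibres and pattern.
qc_fixture <- function(n_nuclei, seed = 1, image_size = 128) {
  spec <- cell_spec("crossbow", image_size = image_size,
                    n_nuclei = n_nuclei, nucleus_radius = 10,
                    noise_sd = 3, seed = seed)
  generate_micropattern_cell(spec)
}

# Independent rank-formula oracle for the Kruskal-Wallis H (with the
# standard tie correction), written directly from the definition.
kw_oracle <- function(groups) {
  x <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  N <- length(x)
  r <- rank(x)
  h <- 12 / (N * (N + 1)) *
    sum(tapply(r, g, sum)^2 / tapply(r, g, length)) - 3 * (N + 1)
  ties <- table(x)
  correction <- 1 - sum(ties^3 - ties) / (N^3 - N)
  h / correction
}

# Independent direct-formula oracle for Dunn's pairwise z statistics.
dunn_oracle <- function(groups) {
  x <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  N <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  ns <- tapply(r, g, length)
  ties <- table(x)
  v0 <- N * (N + 1) / 12 - sum(ties^3 - ties) / (12 * (N - 1))
  pairs <- utils::combn(seq_along(groups), 2)
  apply(pairs, 2, function(pr) {
    num <- rbar[pr[1]] - rbar[pr[2]]
    if (num == 0) return(0)
    num / sqrt(v0 * (1 / ns[pr[1]] + 1 / ns[pr[2]]))
  })
}
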