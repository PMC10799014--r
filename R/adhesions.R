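#' Detect and measure focal adhesions
#'
#' Thresholds a vinculin (or similar adhesion-marker) image, labels
#' 8-connected components of at least `min_area` pixels, and fits an
#' equivalent ellipse to each component from its background-subtracted,
#' intensity-weighted second-order moments: length and width are the full
#' widths at half maximum of the equivalent Gaussian punctum along the
#' major and minor principal axes (`2.355 * sqrt` of the principal
#' variances, the natural scale for diffraction-limited adhesion puncta),
#' orientation is the major-axis angle.
#'
#' @param image Single-channel numeric matrix.
#' @param min_area Minimum component area in pixels.
#' @param pixel_size Micrometres per pixel.
#' @param threshold_method Passed to [auto_threshold()].
#' @param threshold Explicit threshold overriding the automatic one.
#' @param cell_id Identifier copied into the output.
#' @return An `adhesion_set` tibble: `cell_id`, `adhesion_id`, `x`, `y`,
#'   `length_px`, `width_px`, `orientation_deg`, `area_px`, `length_um`,
#'   `width_um`, `area_um2`. Empty or constant image: zero rows.
#' @export
detect_adhesions <- function(image, min_area = 4, pixel_size = 1,
                             threshold_method = "half_max", threshold = NULL,
                             cell_id = NA_character_) {
  check_image(image)
  empty <- tibble::tibble(
    cell_id = character(), adhesion_id = integer(), x = numeric(),
    y = numeric(), length_px = numeric(), width_px = numeric(),
    orientation_deg = numeric(), area_px = integer(),
    length_um = numeric(), width_um = numeric(), area_um2 = numeric()
  )
  class(empty) <- c("adhesion_set", class(empty))
  thr <- if (is.null(threshold)) auto_threshold(image, threshold_method) else threshold
  if (is.na(thr)) return(empty)
  mask <- image > thr
  if (!any(mask)) return(empty)
  bg <- median(image)
  lab <- as.integer(label_components8(mask))
  nx <- nrow(image)
  px <- which(lab > 0)
  groups <- split(px, lab[px])
  recs <- lapply(groups, function(ii) {
    if (length(ii) < min_area) return(NULL)
    xs <- ((ii - 1) %% nx) + 1
    ys <- ((ii - 1) %/% nx) + 1
    coords <- cbind(xs, ys)
    ctr <- colMeans(coords)
    cc <- sweep(coords, 2, ctr)
    cv <- crossprod(cc) / nrow(cc) + diag(1 / 12, 2)
    e <- eigen(cv, symmetric = TRUE)
    ang <- atan2(e$vectors[2, 1], e$vectors[1, 1])
    crude_major <- 4 * sqrt(e$values[1])
    crude_minor <- 4 * sqrt(e$values[2])
    # refine both axes with 1-D intensity moments through the centroid:
    # subpixel, and far less sensitive to background error than 2-D moments
    major <- axis_fwhm(image, ctr, ang, 0.75 * crude_major + 3, bg)
    minor <- axis_fwhm(image, ctr, ang + pi / 2, 0.75 * crude_minor + 3, bg)
    if (is.na(major)) major <- crude_major
    if (is.na(minor)) minor <- crude_minor
    if (minor > major) { tmp <- major; major <- minor; minor <- tmp }
    ori <- fold_orientation(ang * 180 / pi)
    list(x = unname(ctr[1]), y = unname(ctr[2]), length_px = major,
         width_px = minor, orientation_deg = ori, area_px = length(ii))
  })
  recs <- recs[!vapply(recs, is.null, logical(1))]
  if (length(recs) == 0) return(empty)
  tb <- tibble::tibble(
    cell_id = cell_id,
    adhesion_id = seq_along(recs),
    x = vapply(recs, `[[`, numeric(1), "x"),
    y = vapply(recs, `[[`, numeric(1), "y"),
    length_px = vapply(recs, `[[`, numeric(1), "length_px"),
    width_px = vapply(recs, `[[`, numeric(1), "width_px"),
    orientation_deg = vapply(recs, `[[`, numeric(1), "orientation_deg"),
    area_px = vapply(recs, function(r) as.integer(r$area_px), integer(1))
  )
  tb$length_um <- tb$length_px * pixel_size
  tb$width_um <- tb$width_px * pixel_size
  tb$area_um2 <- tb$area_px * pixel_size^2
  class(tb) <- c("adhesion_set", class(tb))
  attr(tb, "pixel_size") <- pixel_size
  tb
}


# FWHM of the equivalent Gaussian along one axis: intensity-weighted second
# moment of the background-subtracted 1-D profile through `ctr` at angle
# `ang`, sampled by bilinear interpolation; 1/6 corrects the triangle-kernel
# reconstruction variance.
axis_fwhm <- function(image, ctr, ang, half, bg) {
  offs <- seq(-half, half, by = 0.5)
  xs <- ctr[1] + offs * cos(ang)
  ys <- ctr[2] + offs * sin(ang)
  ok <- xs >= 1 & xs <= nrow(image) & ys >= 1 & ys <= ncol(image)
  if (sum(ok) < 5) return(NA_real_)
  v <- bilinear(image, xs[ok], ys[ok]) - bg
  if (sum(v) <= 0) return(NA_real_)
  mu <- sum(offs[ok] * v) / sum(v)
  s2 <- sum((offs[ok] - mu)^2 * v) / sum(v)
  if (!is.finite(s2) || s2 <= 1 / 6) return(NA_real_)
  2.355 * sqrt(s2 - 1 / 6)
}

#' Count proximity-ligation (PLA) foci
#'
#' The foci-counting macro: median prefilter, Gaussian blur, Kapur
#' maximum-entropy automatic threshold, then an 8-connected particle count
#' with minimum/maximum size gates. The count is invariant to global
#' intensity scaling since the threshold is histogram-shape based.
#'
#' @param image Single-channel numeric matrix.
#' @param median_radius Median prefilter radius in pixels (0 = off).
#' @param blur_sigma Gaussian blur sigma in pixels.
#' @param size_gates Length-2 numeric, min and max particle area in pixels.
#' @param cell_id Identifier copied into the output.
#' @return A `foci_count` tibble with one row: `cell_id`, `n_foci`, and a
#'   `centres` list-column (tibble of x, y per focus). A constant
#'   (saturated or blank) image counts zero with a warning.
#' @export
count_foci <- function(image, median_radius = 1, blur_sigma = 1,
                       size_gates = c(4, 10000), cell_id = NA_character_) {
  check_image(image)
  zero <- tibble::tibble(
    cell_id = cell_id, n_foci = 0L,
    centres = list(tibble::tibble(x = numeric(), y = numeric()))
  )
  class(zero) <- c("foci_count", class(zero))
  if (diff(range(image)) == 0) {
    warn("constant image: no foci counted")
    return(zero)
  }
  work <- image
  if (median_radius > 0) {
    rng <- range(work)
    sc <- (work - rng[1]) / diff(rng)
    work <- as.matrix(EBImage::medianFilter(sc, median_radius)) * diff(rng) + rng[1]
  }
  if (blur_sigma > 0) work <- as.matrix(EBImage::gblur(work, blur_sigma))
  thr <- auto_threshold(work, "max_entropy")
  if (is.na(thr)) return(zero)
  mask <- work > thr
  if (!any(mask)) return(zero)
  lab <- as.integer(label_components8(mask))
  areas <- tabulate(lab)
  keep <- which(areas >= size_gates[1] & areas <= size_gates[2])
  if (length(keep)) {
    # amplitude gate: a focus must rise well above the smoothed-noise floor,
    # otherwise blurred background noise can form above-threshold blobs
    floor_gate <- median(work) + 6 * stats::mad(work)
    peaks <- vapply(keep, function(kk) max(work[lab == kk]), numeric(1))
    keep <- keep[peaks >= floor_gate]
  }
  if (length(keep) == 0) return(zero)
  nx <- nrow(image)
  px <- which(lab > 0 & lab %in% keep)
  g <- split(px, match(lab[px], keep))
  centres <- tibble::tibble(
    x = vapply(g, function(ii) mean(((ii - 1) %% nx) + 1), numeric(1)),
    y = vapply(g, function(ii) mean(((ii - 1) %/% nx) + 1), numeric(1))
  )
  out <- tibble::tibble(cell_id = cell_id, n_foci = length(keep),
                        centres = list(centres))
  class(out) <- c("foci_count", class(out))
  out
}
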