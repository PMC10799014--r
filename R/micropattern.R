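#' Bundle the channels of one micropatterned cell
#'
#' Container for a single cell's multi-channel image together with its QC
#' status and the centring translation applied so far. All channels must
#' share dimensions. Downstream aggregation ([build_frequency_map()])
#' requires `qc_status == "passed"`.
#'
#' @param channels Named list of numeric matrices, one per stain.
#' @param pixel_size Micrometres per pixel.
#' @param cell_id Identifier carried into result tables.
#' @param qc_status One of `"passed"`, `"excluded_multinucleate"`,
#'   `"excluded_mitotic"`, `"excluded_offpattern"` (or `"pending"` before QC).
#' @return A `cell_image_set`.
#' @export
cell_image_set <- function(channels, pixel_size = 1, cell_id = NA_character_,
                           qc_status = "pending") {
  stopifnot(is.list(channels), length(channels) >= 1,
            !is.null(names(channels)))
  dims <- vapply(channels, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    abort("all channels must share dimensions")
  }
  lapply(channels, check_image)
  structure(
    list(channels = channels, pixel_size = pixel_size, cell_id = cell_id,
         qc_status = qc_status, centring_offset = c(dx = 0, dy = 0)),
    class = "cell_image_set"
  )
}

#' @export
print.cell_image_set <- function(x, ...) {
  cat(sprintf("<cell_image_set> %s: %d channel(s) [%s], %dx%d px, qc = %s, offset = (%d, %d)\n",
              x$cell_id, length(x$channels),
              paste(names(x$channels), collapse = ", "),
              nrow(x$channels[[1]]), ncol(x$channels[[1]]),
              x$qc_status, x$centring_offset[1], x$centring_offset[2]))
  invisible(x)
}

#' Filter and threshold one channel
#'
#' The first step of the reference-cell macro: an optional median prefilter,
#' a Gaussian blur, then an automatic histogram threshold (bright objects on
#' dark background). With `gaussian_sigma = 0` the image passes through the
#' blur unchanged.
#'
#' @param image Numeric matrix.
#' @param gaussian_sigma Blur sigma in pixels (>= 0).
#' @param threshold_method Passed to [auto_threshold()].
#' @param median_radius Radius of the optional median prefilter (0 = off).
#' @return List with `filtered` (matrix), `mask` (logical matrix of pixels
#'   above the threshold) and `threshold`. A constant image yields an empty
#'   mask with a warning.
#' @export
preprocess <- function(image, gaussian_sigma = 2, threshold_method = "huang",
                       median_radius = 0) {
  check_image(image)
  stopifnot(gaussian_sigma >= 0)
  filtered <- image
  if (median_radius > 0) {
    rng <- range(filtered)
    if (diff(rng) > 0) {
      sc <- (filtered - rng[1]) / diff(rng)
      filtered <- as.matrix(EBImage::medianFilter(sc, median_radius)) *
        diff(rng) + rng[1]
    }
  }
  if (gaussian_sigma > 0) {
    filtered <- as.matrix(EBImage::gblur(filtered, sigma = gaussian_sigma))
  }
  thr <- auto_threshold(filtered, threshold_method)
  if (is.na(thr)) {
    mask <- matrix(FALSE, nrow(image), ncol(image))
  } else {
    mask <- filtered > thr
  }
  list(filtered = filtered, mask = mask, threshold = thr)
}

#' Nucleus-based quality control of one cell
#'
#' Counts nuclei in the DAPI channel and classifies the cell. Cells with two
#' or more nuclei are excluded as multinucleate; a cell without a nucleus is
#' off pattern. A single nucleus is flagged mitotic when its area falls
#' below half a reference (cohort median) area while its solidity exceeds
#' `solidity_max` — condensed chromatin is small and compact. Without a
#' reference area the mitotic flag is not applied.
#'
#' @param dapi_image DAPI channel matrix.
#' @param min_area Minimum component area in pixels to count as a nucleus.
#' @param area_ref Reference nucleus area in pixels (e.g. cohort median), or
#'   `NULL` to skip the mitotic check.
#' @param solidity_max Solidity above which a small nucleus is called
#'   condensed.
#' @param threshold Intensity threshold; `NULL` for automatic (`half_max`,
#'   which returns an empty mask on a nucleus-free noise field where
#'   histogram-shape methods would hallucinate objects).
#' @return A QC status string (see [cell_image_set()]).
#' @export
qc_cell <- function(dapi_image, min_area = 25, area_ref = NULL,
                    solidity_max = 0.95, threshold = NULL) {
  check_image(dapi_image)
  thr <- if (is.null(threshold)) auto_threshold(dapi_image, "half_max") else threshold
  if (is.na(thr)) return("excluded_offpattern")
  mask <- dapi_image > thr
  lab <- EBImage::bwlabel(mask)
  areas <- tabulate(as.integer(lab))
  keep <- which(areas >= min_area)
  if (length(keep) == 0) return("excluded_offpattern")
  if (length(keep) >= 2) return("excluded_multinucleate")
  if (!is.null(area_ref)) {
    area <- areas[keep]
    if (area < 0.5 * area_ref) {
      px <- which(lab == keep, arr.ind = TRUE)
      hull <- grDevices::chull(px[, 1], px[, 2])
      hull_area <- polygon_area(px[hull, 1], px[hull, 2])
      solidity <- if (hull_area > 0) area / hull_area else 1
      if (solidity > solidity_max) return("excluded_mitotic")
    }
  }
  "passed"
}

#' Run QC over a cohort of cells
#'
#' Applies [qc_cell()] to every cell, using the cohort's median nucleus area
#' as the mitotic reference, and records the status on each cell.
#'
#' @param cells List of [cell_image_set()] objects with a `dapi` channel.
#' @param dapi_channel Name of the DAPI channel.
#' @param ... Passed to [qc_cell()].
#' @return The list of cells with updated `qc_status`, with a `qc` attribute
#'   holding a tibble (cell_id, qc_status).
#' @export
qc_cohort <- function(cells, dapi_channel = "dapi", ...) {
  areas <- vapply(cells, function(cl) {
    thr <- auto_threshold(cl$channels[[dapi_channel]], "half_max")
    if (is.na(thr)) return(NA_real_)
    lab <- EBImage::bwlabel(cl$channels[[dapi_channel]] > thr)
    a <- tabulate(as.integer(lab))
    if (length(a)) max(a) else NA_real_
  }, numeric(1))
  ref <- median(areas, na.rm = TRUE)
  cells <- lapply(cells, function(cl) {
    cl$qc_status <- qc_cell(cl$channels[[dapi_channel]], area_ref = ref, ...)
    cl
  })
  attr(cells, "qc") <- tibble::tibble(
    cell_id = vapply(cells, function(cl) as.character(cl$cell_id), character(1)),
    qc_status = vapply(cells, function(cl) cl$qc_status, character(1))
  )
  cells
}

#' Centre a cell on its micropattern
#'
#' Finds the integer translation maximising the cross-correlation between a
#' pattern channel and a pattern template and applies it to every channel,
#' recording the offset. Centring an already-centred cell is a no-op (offset
#' within one pixel). If, after centring, the overlap between the
#' thresholded pattern channel and the template is below `min_overlap`, the
#' cell is marked off pattern and returned unshifted.
#'
#' @param cell A [cell_image_set()].
#' @param template Logical or 0/1 matrix of the pattern at its reference
#'   position (e.g. `crossbow_pattern()$mask`), same dimensions as the cell.
#' @param channel Name of the channel imaging the pattern.
#' @param min_overlap Minimum fraction of template pixels covered by the
#'   centred, thresholded pattern channel.
#' @return The cell, shifted, with `centring_offset` updated.
#' @export
center_on_pattern <- function(cell, template, channel = "pattern",
                              min_overlap = 0.5) {
  stopifnot(inherits(cell, "cell_image_set"))
  img <- cell$channels[[channel]]
  if (is.null(img)) abort(sprintf("channel '%s' not present", channel))
  stopifnot(all(dim(img) == dim(template)))
  tmpl <- (template > 0) * 1
  sh <- best_shift(tmpl, img)
  thr <- auto_threshold(img, "huang")
  if (is.na(thr)) {
    cell$qc_status <- "excluded_offpattern"
    return(cell)
  }
  shifted_mask <- shift_image((img > thr) * 1, sh["dx"], sh["dy"]) > 0
  overlap <- sum(shifted_mask & tmpl > 0) / sum(tmpl > 0)
  if (overlap < min_overlap) {
    cell$qc_status <- "excluded_offpattern"
    return(cell)
  }
  cell$channels <- lapply(cell$channels, function(ch) {
    shift_image(ch, sh["dx"], sh["dy"], fill = median(ch))
  })
  cell$centring_offset <- cell$centring_offset + c(dx = unname(sh["dx"]),
                                                   dy = unname(sh["dy"]))
  cell
}

#' Translation-only registration of an image stack
#'
#' Registers every image to the first by the peak of the normalised
#' cross-correlation, at integer-pixel resolution — the rigid alignment of
#' the original macro restricted to translation, which suffices for centred
#' micropattern images.
#'
#' @param images List of numeric matrices with common dimensions.
#' @param fill Fill value for pixels shifted in from outside (default: each
#'   image's median).
#' @return List with `aligned` (list of matrices) and `shifts` (tibble:
#'   image, dx, dy).
#' @export
register_stack <- function(images, fill = NULL) {
  stopifnot(is.list(images), length(images) >= 1)
  lapply(images, check_image)
  dims <- vapply(images, dim, integer(2))
  if (any(dims != dims[, 1])) abort("all images must share dimensions")
  ref <- images[[1]]
  shifts <- lapply(images, function(im) best_shift(ref, im))
  aligned <- purrr::map2(images, shifts, function(im, sh) {
    f <- if (is.null(fill)) median(im) else fill
    shift_image(im, sh["dx"], sh["dy"], fill = f)
  })
  list(
    aligned = aligned,
    shifts = tibble::tibble(
      image = seq_along(images),
      dx = vapply(shifts, `[`, numeric(1), "dx"),
      dy = vapply(shifts, `[`, numeric(1), "dy")
    )
  )
}

#' Build a per-channel frequency map (reference cell)
#'
#' Pixel-wise projection of one channel across many centred, QC-passed
#' cells, rescaled min–max to integers 0–255. The mean projection renders
#' pixel-intensity frequency across the cohort — where a stain recurrently
#' localises on the pattern; a max projection is also available.
#'
#' @param cells List of [cell_image_set()] objects, all `qc_status ==
#'   "passed"`, centred, with common dimensions.
#' @param channel Channel name to aggregate.
#' @param projection `"mean"` or `"max"`.
#' @return A `frequency_map`: list with `map` (integer matrix 0–255),
#'   `channel`, `n_cells`, `projection`.
#' @export
build_frequency_map <- function(cells, channel, projection = c("mean", "max")) {
  projection <- match.arg(projection)
  if (length(cells) == 0) abort("no cells to aggregate")
  status <- vapply(cells, function(cl) cl$qc_status, character(1))
  if (any(status != "passed")) {
    abort("all cells must have qc_status 'passed' before aggregation")
  }
  mats <- lapply(cells, function(cl) {
    m <- cl$channels[[channel]]
    if (is.null(m)) abort(sprintf("channel '%s' missing in a cell", channel))
    m
  })
  dims <- vapply(mats, dim, integer(2))
  if (any(dims != dims[, 1])) abort("all cells must share dimensions")
  proj <- if (projection == "mean") {
    Reduce(`+`, mats) / length(mats)
  } else {
    Reduce(pmax, mats)
  }
  rng <- range(proj)
  map <- if (diff(rng) > 0) {
    matrix(as.integer(round((proj - rng[1]) / diff(rng) * 255)),
           nrow(proj), ncol(proj))
  } else {
    warn("constant projection: frequency map is all zero")
    matrix(0L, nrow(proj), ncol(proj))
  }
  structure(
    list(map = map, channel = channel, n_cells = length(cells),
         projection = projection),
    class = "frequency_map"
  )
}

#' @export
print.frequency_map <- function(x, ...) {
  cat(sprintf("<frequency_map> channel '%s': %dx%d px, %s projection of %d cell(s), range %d-%d\n",
              x$channel, nrow(x$map), ncol(x$map), x$projection, x$n_cells,
              min(x$map), max(x$map)))
  invisible(x)
}
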