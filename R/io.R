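#' Write channels or frames as a multi-page TIFF
#'
#' One page per channel (or time point), stored at the given bit depth.
#' Intensities are assumed to lie in `[0, 2^bit_depth - 1]`.
#'
#' @param images Named list of matrices (`img[x, y]` convention) or a single
#'   matrix.
#' @param path Output file path.
#' @param bit_depth 8 or 16.
#' @return `path`, invisibly.
#' @export
write_image_tiff <- function(images, path, bit_depth = 8) {
  if (is.matrix(images)) images <- list(images)
  maxv <- 2^bit_depth - 1
  pages <- lapply(images, function(m) t(pmin(pmax(round(m), 0), maxv)) / maxv)
  tiff::writeTIFF(pages, path, bits.per.sample = bit_depth)
  invisible(path)
}

#' Read a multi-page TIFF
#'
#' @param path File path.
#' @param bit_depth Bit depth used to rescale back to intensity counts.
#' @param names Optional page names.
#' @return Named list of matrices in the package's `img[x, y]` convention.
#' @export
read_image_tiff <- function(path, bit_depth = 8, names = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  out <- lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]
    t(p) * (2^bit_depth - 1)
  })
  if (!is.null(names)) names(out) <- names
  out
}

#' Write generator ground truth as JSON
#'
#' Serialises the parameter record of a synthetic image (spec echo, object
#' tables, pattern geometry, summary counts). Pixel masks are indices into
#' the image and are omitted by default to keep sidecar files small.
#'
#' @param truth A `ground_truth` object.
#' @param path Output path.
#' @param masks Include per-object pixel masks.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path, masks = FALSE) {
  stopifnot(inherits(truth, "ground_truth"))
  payload <- unclass(truth)
  payload$pattern_mask <- NULL
  if (!masks) payload$masks <- NULL
  payload$spec <- lapply(unclass(payload$spec), function(el) {
    if (is.list(el) && length(el) && inherits(el[[1]], "fibre_spec")) {
      lapply(el, unclass)
    } else if (is.list(el) && length(el) && inherits(el[[1]], "adhesion_spec")) {
      lapply(el, unclass)
    } else el
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
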