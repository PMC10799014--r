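#' Segment the wound in one frame
#'
#' Two segmentation modes for scratch-assay frames with a roughly vertical
#' wound:
#'
#' * `brightfield_texture` — cells are textured, the cell-free wound is
#'   smooth: a local-variance filter (Gaussian moments, window
#'   `window_sigma`) is thresholded (Otsu on the local standard deviation)
#'   and the low-variance region is the wound candidate. Because the
#'   classification ranks variance, it is invariant to global intensity
#'   scaling.
#' * `fluorescence_threshold` — with a live F-actin stain (e.g. SiR-actin)
#'   the wound is simply the low-intensity region under an automatic
#'   threshold.
#'
#' The largest connected candidate region is retained. If no candidate
#' region of at least `min_frac` of the frame exists, or the candidate is
#' not separable from the cell region, the wound is reported closed
#' (area 0) with a warning. Width statistics are taken per image row: the
#' mean and standard deviation of the wound chord across rows.
#'
#' @param frame Numeric matrix.
#' @param mode Segmentation mode (above).
#' @param pixel_size Micrometres per pixel.
#' @param window_sigma Gaussian window sigma for the variance filter.
#' @param min_frac Minimum wound area as a fraction of the frame.
#' @param t Optional time stamp (hours) stored in the result.
#' @return A `wound_frame`: list with `mask` (logical), `area_um2`,
#'   `width_um`, `width_sd_um`, `t`, `pixel_size`.
#' @export
segment_wound <- function(frame,
                          mode = c("brightfield_texture", "fluorescence_threshold"),
                          pixel_size = 1, window_sigma = 3, min_frac = 0.002,
                          t = NA_real_) {
  mode <- match.arg(mode)
  check_image(frame)
  nx <- nrow(frame); ny <- ncol(frame)
  closed <- structure(
    list(mask = matrix(FALSE, nx, ny), area_um2 = 0, width_um = 0,
         width_sd_um = 0, t = t, pixel_size = pixel_size),
    class = "wound_frame")
  if (mode == "brightfield_texture") {
    mu <- as.matrix(EBImage::gblur(frame, window_sigma))
    mu2 <- as.matrix(EBImage::gblur(frame^2, window_sigma))
    feat <- sqrt(pmax(mu2 - mu^2, 0))
  } else {
    feat <- frame
  }
  flo <- quantile(feat, 0.01, names = FALSE)
  fhi <- quantile(feat, 0.90, names = FALSE)
  if (!is.finite(fhi - flo) || fhi - flo <= 0) {
    warn("featureless frame: reporting a closed wound")
    return(closed)
  }
  cand <- feat <= flo + 0.25 * (fhi - flo)
  if (!any(cand)) {
    warn("no candidate wound region: reporting a closed wound")
    return(closed)
  }
  lab <- as.integer(EBImage::bwlabel(cand * 1))
  areas <- tabulate(lab)
  big <- which.max(areas)
  mask <- matrix(lab == big, nx, ny)
  if (sum(mask) < min_frac * nx * ny) {
    warn("largest low-signal region is negligible: reporting a closed wound")
    return(closed)
  }
  # separability guard: the candidate must be clearly darker/smoother than
  # the rest of the frame, otherwise the frame is confluent
  fin <- median(feat[mask])
  fout <- median(feat[!mask])
  if (!is.finite(fout) || fout <= 0 || fin > 0.5 * fout) {
    warn("wound region not separable from cells: reporting a closed wound")
    return(closed)
  }
  if (mode == "brightfield_texture") {
    # the local sd peaks exactly at the cell-wound boundary (maximal mixing
    # inside the window), so the wound edge in each row is localised at the
    # flanking variance peaks, with parabolic subpixel refinement; a plain
    # threshold crossing would sit several window-sigmas inside the wound
    search <- ceiling(4 * window_sigma)
    chords <- vapply(seq_len(ny), function(y) {
      cols <- which(mask[, y])
      if (length(cols) == 0) return(0)
      lo <- min(cols); hi <- max(cols)
      p <- feat[, y]
      xl <- peak_position(p, max(1, lo - search), min(nx, lo + search))
      xr <- peak_position(p, max(1, hi - search), min(nx, hi + search))
      max(xr - xl, 0)
    }, numeric(1))
    area_px <- sum(chords)
    wmean <- mean(chords)
    wsd <- sd(chords)
  } else {
    chords <- colSums(mask)
    area_px <- sum(mask)
    wmean <- mean(chords)
    wsd <- sd(chords)
  }
  structure(
    list(mask = mask,
         area_um2 = area_px * pixel_size^2,
         width_um = wmean * pixel_size,
         width_sd_um = wsd * pixel_size,
         t = t, pixel_size = pixel_size),
    class = "wound_frame")
}

# Argmax of v over [lo, hi] with 3-point parabolic subpixel refinement.
peak_position <- function(v, lo, hi) {
  seg <- v[lo:hi]
  i <- which.max(seg)
  x <- lo + i - 1
  if (x > 1 && x < length(v)) {
    a <- v[x - 1]; b <- v[x]; c <- v[x + 1]
    den <- a - 2 * b + c
    if (den < 0) x <- x + 0.5 * (a - c) / den
  }
  x
}

#' Measure a whole wound time lapse
#'
#' Runs [segment_wound()] on every frame and assembles the per-frame
#' metrics.
#'
#' @param frames List of matrices (one per time point).
#' @param dt Hours between frames.
#' @param t0 Time of the first frame in hours (e.g. hours after wounding).
#' @param ... Passed to [segment_wound()].
#' @return A `wound_series` tibble: `frame`, `t`, `area_um2`, `width_um`,
#'   `width_sd_um`.
#' @export
measure_wound_series <- function(frames, dt = 1, t0 = 0, ...) {
  stopifnot(is.list(frames), length(frames) >= 1)
  rows <- purrr::imap(frames, function(fr, i) {
    wf <- segment_wound(fr, t = t0 + (i - 1) * dt, ...)
    tibble::tibble(frame = i, t = wf$t, area_um2 = wf$area_um2,
                   width_um = wf$width_um, width_sd_um = wf$width_sd_um)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("wound_series", class(out))
  out
}

#' Wound closure percentage
#'
#' The scratch-assay closure equation: `(A_t0 - A_t) / A_t0 * 100`.
#' Negative values (a growing wound) are reported as-is.
#'
#' @param area_t0 Initial wound area (must be positive).
#' @param area_t Wound area at the later time point(s); vectorised.
#' @return Closure percentage(s).
#' @export
closure_pct <- function(area_t0, area_t) {
  if (any(area_t0 <= 0)) abort("initial wound area must be positive")
  (area_t0 - area_t) / area_t0 * 100
}

#' Cell migration rate
#'
#' The scratch-assay migration equation: `(W_i - W_f) / t`, with the
#' initial and final mean wound widths in micrometres and the assay time
#' span in hours.
#'
#' @param width_initial Initial mean wound width, micrometres.
#' @param width_final Final mean wound width, micrometres.
#' @param t_span Time span in hours (must be positive).
#' @return Migration rate in micrometres per hour.
#' @export
migration_rate <- function(width_initial, width_final, t_span) {
  if (any(t_span <= 0)) abort("time span must be positive")
  (width_initial - width_final) / t_span
}

#' Kinetic summary of a measured wound series
#'
#' Computes the closure curve and the migration rate from a
#' [measure_wound_series()] table (or any tibble with `t`, `area_um2`,
#' `width_um`). The final width is taken from the last analysed frame; if
#' the wound closes early (width reaches zero), the time span ends at the
#' first closed frame, so the rate reflects time-to-closure.
#'
#' @param series A `wound_series` tibble.
#' @return A `wound_kinetics` object: list with `curve` (tibble `frame`,
#'   `t`, `area_um2`, `width_um`, `closure_pct`), `migration_rate_um_h`,
#'   `t_span_h`, `closed` (logical).
#' @export
wound_kinetics <- function(series) {
  if (nrow(series) < 2) abort("need at least two frames for kinetics")
  if (series$area_um2[1] <= 0) abort("initial wound area is zero: closure undefined")
  curve <- dplyr::mutate(series,
                         closure_pct = closure_pct(series$area_um2[1], .data$area_um2))
  closed_at <- which(series$width_um <= 0)
  if (length(closed_at)) {
    k <- min(closed_at)
    t_span <- series$t[k] - series$t[1]
    w_f <- 0
  } else {
    k <- nrow(series)
    t_span <- series$t[k] - series$t[1]
    w_f <- series$width_um[k]
  }
  structure(
    list(curve = curve,
         migration_rate_um_h = migration_rate(series$width_um[1], w_f, t_span),
         t_span_h = t_span,
         closed = length(closed_at) > 0),
    class = "wound_kinetics")
}

#' @export
print.wound_kinetics <- function(x, ...) {
  cat(sprintf("<wound_kinetics> %d frames over %.1f h: migration rate %.2f um/h, final closure %.1f%%%s\n",
              nrow(x$curve), x$t_span_h, x$migration_rate_um_h,
              x$curve$closure_pct[nrow(x$curve)],
              if (x$closed) " (closed)" else ""))
  invisible(x)
}

#' @rdname wound_kinetics
#' @param x A `wound_kinetics` object.
#' @param ... Unused.
#' @method glance wound_kinetics
#' @export
glance.wound_kinetics <- function(x, ...) {
  tibble::tibble(
    migration_rate_um_h = x$migration_rate_um_h,
    t_span_h = x$t_span_h,
    final_closure_pct = x$curve$closure_pct[nrow(x$curve)],
    closed = x$closed,
    n_frames = nrow(x$curve)
  )
}

#' @rdname wound_kinetics
#' @method tidy wound_kinetics
#' @export
tidy.wound_kinetics <- function(x, ...) x$curve
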