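#' Detect and measure linear filaments
#'
#' Segments bright linear structures (stress fibres) and reports one record
#' per filament: centre, geodesic length, width and orientation, in the
#' spirit of single-filament analysis tools. Pipeline: optional Gaussian
#' smoothing, automatic threshold, Zhang–Suen skeletonisation, removal of
#' junction pixels so crossing fibres split into separate records, and
#' per-branch tracing.
#'
#' Estimators: length is the smoothed chain length of the traced skeleton
#' plus one binary width (the skeleton of an elongated object retracts about
#' half a width at each end); width is the full width at half maximum
#' implied by perpendicular intensity moments sampled along the trace on
#' the raw image (subpixel; the Euclidean distance transform of the binary
#' mask serves as the initial gauge and fallback); orientation is the
#' principal axis of the traced pixels, folded to `[-90, 90)` degrees with
#' the x-axis horizontal and y increasing downward.
#'
#' @param image Single-channel numeric matrix.
#' @param pixel_size Micrometres per pixel (1 reports pixel units).
#' @param min_length Minimum filament length in pixels.
#' @param sigma Gaussian smoothing sigma before thresholding (0 = none);
#'   affects segmentation only, widths are measured on the raw image.
#' @param min_spur Terminal skeleton branches shorter than this (pixels)
#'   hanging off junctions are pruned as thinning artefacts.
#' @param threshold_method Passed to [auto_threshold()]; the default
#'   `half_max` cuts Gaussian-profile fibres at their full width at half
#'   maximum.
#' @param threshold Explicit threshold overriding the automatic one.
#' @param cell_id Identifier copied into the output.
#' @return A `filament_set` tibble: one row per filament with columns
#'   `cell_id`, `filament_id`, `x`, `y`, `length_px`, `width_px`,
#'   `orientation_deg`, `length_um`, `width_um`, `n_px` and a `trace`
#'   list-column of ordered pixel coordinates. Empty image: zero rows.
#' @export
detect_filaments <- function(image, pixel_size = 1, min_length = 10,
                             sigma = 1, min_spur = 5,
                             threshold_method = "half_max",
                             threshold = NULL, cell_id = NA_character_) {
  check_image(image)
  work <- if (sigma > 0) as.matrix(EBImage::gblur(image, sigma)) else image
  thr <- if (is.null(threshold)) auto_threshold(work, threshold_method) else threshold
  empty <- filament_set_tibble(NULL, pixel_size)
  if (is.na(thr)) return(empty)
  mask <- work > thr
  if (!any(mask)) return(empty)
  skel <- prune_skeleton(skeletonize(mask), min_spur = min_spur)
  sp <- split_skeleton(skel)
  if (sp$n_branches == 0) return(empty)
  dt <- as.matrix(EBImage::distmap(mask * 1))
  lab <- as.integer(sp$branch_lab)
  px <- which(lab > 0)
  nx <- nrow(image)
  coords_all <- cbind(((px - 1) %% nx) + 1, ((px - 1) %/% nx) + 1)
  bg <- median(image)
  recs <- lapply(split(seq_along(px), lab[px]), function(ii) {
    coords <- trace_branch(coords_all[ii, , drop = FALSE])
    dts <- dt[cbind(coords[, 1], coords[, 2])]
    # the distance transform dips near the fibre end caps; gauge the binary
    # half-width on the central portion of the trace when it is long enough
    trim <- ceiling(2 * stats::median(dts))
    dts_c <- if (nrow(coords) > 3 * trim && trim > 0) {
      dts[(trim + 1):(length(dts) - trim)]
    } else dts
    w_bin <- max(2 * mean(dts_c) - 1, 1)
    w <- profile_width(image, coords, bg, w_bin) %||% w_bin
    len <- chain_length(coords) + w_bin
    if (len < min_length) return(NULL)
    ctr <- colMeans(coords)
    ori <- principal_angle(coords)
    list(x = ctr[1], y = ctr[2], length_px = len, width_px = w,
         orientation_deg = ori, n_px = nrow(coords), trace = coords)
  })
  recs <- recs[!vapply(recs, is.null, logical(1))]
  out <- filament_set_tibble(recs, pixel_size, cell_id)
  out
}

filament_set_tibble <- function(recs, pixel_size, cell_id = NA_character_) {
  if (is.null(recs) || length(recs) == 0) {
    tb <- tibble::tibble(
      cell_id = character(), filament_id = integer(),
      x = numeric(), y = numeric(),
      length_px = numeric(), width_px = numeric(), orientation_deg = numeric(),
      length_um = numeric(), width_um = numeric(), n_px = integer(),
      trace = list()
    )
  } else {
    tb <- tibble::tibble(
      cell_id = cell_id,
      filament_id = seq_along(recs),
      x = vapply(recs, `[[`, numeric(1), "x"),
      y = vapply(recs, `[[`, numeric(1), "y"),
      length_px = vapply(recs, `[[`, numeric(1), "length_px"),
      width_px = vapply(recs, `[[`, numeric(1), "width_px"),
      orientation_deg = vapply(recs, `[[`, numeric(1), "orientation_deg"),
      length_um = NA_real_, width_um = NA_real_,
      n_px = vapply(recs, function(r) as.integer(r$n_px), integer(1)),
      trace = lapply(recs, `[[`, "trace")
    )
    tb$length_um <- tb$length_px * pixel_size
    tb$width_um <- tb$width_px * pixel_size
  }
  class(tb) <- c("filament_set", class(tb))
  attr(tb, "pixel_size") <- pixel_size
  tb
}

# Subpixel filament width from perpendicular intensity moments on the raw
# image: at points along the (smoothed) trace, sample the
# background-subtracted intensity perpendicular to the local direction and
# take 2.355 * the intensity-weighted sd of the offset — the FWHM of the
# equivalent Gaussian cross-section. Free of binarisation discretisation.
profile_width <- function(image, coords, bg, w_bin, n_points = 15) {
  n <- nrow(coords)
  if (n < 5) return(NULL)
  sm <- smooth_trace(coords, 5)
  lo <- max(2, ceiling(w_bin))
  hi <- min(n - 1, n - ceiling(w_bin))
  if (hi - lo < 2) { lo <- 2; hi <- n - 1 }
  pts <- unique(round(seq(lo, hi, length.out = min(n_points, hi - lo + 1))))
  half <- max(2 * w_bin, 4)
  offs <- seq(-half, half, by = 0.5)
  nx <- nrow(image); ny <- ncol(image)
  sds <- vapply(pts, function(i) {
    dirv <- sm[min(i + 1, n), ] - sm[max(i - 1, 1), ]
    nv <- sqrt(sum(dirv^2))
    if (nv == 0) return(NA_real_)
    perp <- c(-dirv[2], dirv[1]) / nv
    xs <- sm[i, 1] + offs * perp[1]
    ys <- sm[i, 2] + offs * perp[2]
    ok <- xs >= 1 & xs <= nx & ys >= 1 & ys <= ny
    if (sum(ok) < 5) return(NA_real_)
    # no clipping: zero-mean noise residuals leave the moments unbiased,
    # whereas clipping at zero adds a positive pedestal across the window
    v <- bilinear(image, xs[ok], ys[ok]) - bg
    if (sum(v) <= 0) return(NA_real_)
    mu <- sum(offs[ok] * v) / sum(v)
    sum((offs[ok] - mu)^2 * v) / sum(v)
  }, numeric(1))
  sds <- sds[is.finite(sds) & sds > 0]
  if (length(sds) == 0) return(NULL)
  # 1/6: variance of the bilinear (triangle-kernel) reconstruction of the
  # pixel-sampled profile
  2.355 * sqrt(max(median(sds) - 1 / 6, 0.09))
}

bilinear <- function(image, xs, ys) {
  nx <- nrow(image); ny <- ncol(image)
  x0 <- pmin(pmax(floor(xs), 1), nx - 1)
  y0 <- pmin(pmax(floor(ys), 1), ny - 1)
  fx <- xs - x0; fy <- ys - y0
  (1 - fx) * (1 - fy) * image[cbind(x0, y0)] +
    fx * (1 - fy) * image[cbind(x0 + 1, y0)] +
    (1 - fx) * fy * image[cbind(x0, y0 + 1)] +
    fx * fy * image[cbind(x0 + 1, y0 + 1)]
}

# Principal-axis angle (degrees, folded to [-90, 90)) of a pixel cloud.
principal_angle <- function(coords) {
  cc <- sweep(coords, 2, colMeans(coords))
  cv <- crossprod(cc) / max(nrow(cc) - 1, 1)
  e <- eigen(cv, symmetric = TRUE)
  v <- e$vectors[, 1]
  fold_orientation(atan2(v[2], v[1]) * 180 / pi)
}

#' Distance from filament centres to the pattern's curved edge
#'
#' Euclidean distance from each filament centre to the nearest point of the
#' crossbow's circular-arc (leading) edge, appended as a column. For a point
#' whose angle from the arc centre falls within the arc span the distance is
#' `|r - R|`; otherwise the nearest arc endpoint is used.
#'
#' @param filaments A `filament_set` (or any tibble with `x`, `y`).
#' @param geometry Arc geometry, e.g. `crossbow_pattern()$geometry` or the
#'   `pattern_geometry` element of a generator ground truth: a list with
#'   `centre`, `radius`, `theta_start`, `theta_end` (degrees, anticlockwise
#'   from +x with y up).
#' @param pixel_size Micrometres per pixel for the `edge_distance_um` column.
#' @return The input with `edge_distance_px` and `edge_distance_um` added.
#' @export
edge_distance <- function(filaments, geometry, pixel_size = NULL) {
  if (is.null(geometry) || is.null(geometry$radius)) {
    abort("no arc geometry available for edge distances")
  }
  ps <- pixel_size %||% attr(filaments, "pixel_size") %||% 1
  d <- point_arc_distance(filaments$x, filaments$y, geometry)
  dplyr::mutate(filaments, edge_distance_px = d, edge_distance_um = d * ps)
}

point_arc_distance <- function(x, y, geometry) {
  cx <- geometry$centre[1]; cy <- geometry$centre[2]
  R <- geometry$radius
  t0 <- geometry$theta_start; t1 <- geometry$theta_end
  phi <- atan2(cy - y, x - cx) * 180 / pi
  r <- sqrt((x - cx)^2 + (y - cy)^2)
  in_span <- ((phi - t0) %% 360) <= (t1 - t0)
  ex0 <- c(cx + R * cos(t0 * pi / 180), cy - R * sin(t0 * pi / 180))
  ex1 <- c(cx + R * cos(t1 * pi / 180), cy - R * sin(t1 * pi / 180))
  d_end <- pmin(sqrt((x - ex0[1])^2 + (y - ex0[2])^2),
                sqrt((x - ex1[1])^2 + (y - ex1[2])^2))
  ifelse(in_span, abs(r - R), d_end)
}

#' Filter records thicker than a width threshold
#'
#' Keeps only records whose width strictly exceeds the threshold (in
#' pixels), for spatial maps of thick actin filaments or large adhesions.
#'
#' @param records Tibble with a `width_px` column (filament or adhesion set).
#' @param width_threshold Width gate in pixels; strict `>` filter.
#' @return Tibble of the retained records (`x`, `y`, widths preserved).
#' @export
thick_object_map <- function(records, width_threshold = 2) {
  dplyr::filter(records, .data$width_px > width_threshold)
}

#' Structure-tensor orientation distribution
#'
#' Local orientation from the smoothed structure tensor: image gradients by
#' central differences after Gaussian smoothing, tensor components averaged
#' with a Gaussian window, per-pixel dominant direction (perpendicular to
#' the gradient eigenvector) weighted by gradient energy and accumulated
#' into bins over `[-90, 90)` degrees. Also reports the energy-weighted
#' circular mean orientation and the global coherence (0 = isotropic,
#' 1 = perfectly aligned).
#'
#' @param image Single-channel numeric matrix.
#' @param bins Number of orientation bins over `[-90, 90)`.
#' @param sigma_grad Pre-smoothing sigma for the gradients (pixels).
#' @param sigma_tensor Smoothing sigma for tensor averaging (pixels).
#' @return An `orientation_histogram`: list with `hist` (tibble: bin_left,
#'   bin_mid, bin_right, weight), `mean_deg`, `coherence`, `total_energy`.
#'   Constant image: zero-mass histogram with a warning.
#' @export
orientation_distribution <- function(image, bins = 18, sigma_grad = 1,
                                     sigma_tensor = 3) {
  check_image(image)
  edges <- seq(-90, 90, length.out = bins + 1)
  empty <- structure(
    list(hist = tibble::tibble(bin_left = edges[-(bins + 1)],
                               bin_right = edges[-1],
                               bin_mid = (edges[-1] + edges[-(bins + 1)]) / 2,
                               weight = rep(0, bins)),
         mean_deg = NA_real_, coherence = NA_real_, total_energy = 0),
    class = "orientation_histogram")
  if (diff(range(image)) == 0) {
    warn("constant image: orientation undefined")
    return(empty)
  }
  sm <- if (sigma_grad > 0) as.matrix(EBImage::gblur(image, sigma_grad)) else image
  gx <- (neighbour_mat(sm, 1, 0) - neighbour_mat(sm, -1, 0)) / 2
  gy <- (neighbour_mat(sm, 0, 1) - neighbour_mat(sm, 0, -1)) / 2
  # drop the one-pixel frame where central differences see the zero padding
  inner <- matrix(FALSE, nrow(sm), ncol(sm))
  inner[2:(nrow(sm) - 1), 2:(ncol(sm) - 1)] <- TRUE
  gx[!inner] <- 0; gy[!inner] <- 0
  jxx <- as.matrix(EBImage::gblur(gx * gx, sigma_tensor))
  jyy <- as.matrix(EBImage::gblur(gy * gy, sigma_tensor))
  jxy <- as.matrix(EBImage::gblur(gx * gy, sigma_tensor))
  energy <- jxx + jyy
  if (sum(energy) == 0) {
    warn("no gradient energy: orientation undefined")
    return(empty)
  }
  theta_grad <- 0.5 * atan2(2 * jxy, jxx - jyy) * 180 / pi
  theta <- fold_orientation(theta_grad + 90)
  w <- as.numeric(energy)
  th <- as.numeric(theta)
  bin <- findInterval(th, edges, rightmost.closed = TRUE, all.inside = TRUE)
  hist_w <- vapply(seq_len(bins), function(b) sum(w[bin == b]), numeric(1))
  c2 <- sum(w * cos(2 * th * pi / 180))
  s2 <- sum(w * sin(2 * th * pi / 180))
  structure(
    list(hist = tibble::tibble(bin_left = edges[-(bins + 1)],
                               bin_right = edges[-1],
                               bin_mid = (edges[-1] + edges[-(bins + 1)]) / 2,
                               weight = hist_w),
         mean_deg = fold_orientation(0.5 * atan2(s2, c2) * 180 / pi),
         coherence = sqrt(c2^2 + s2^2) / sum(w),
         total_energy = sum(w)),
    class = "orientation_histogram"
  )
}

#' @export
print.orientation_histogram <- function(x, ...) {
  cat(sprintf("<orientation_histogram> %d bins over [-90, 90); mean %.1f deg, coherence %.3f\n",
              nrow(x$hist), x$mean_deg, x$coherence))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
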