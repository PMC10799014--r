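#' Describe one synthetic actin fibre
#'
#' A fibre is rendered as a straight line segment with a Gaussian
#' cross-section whose full width at half maximum equals `width`
#' (sigma = width / 2.355), so an intensity-based width measurement at the
#' half-maximum level recovers the declared value. Intensity is truncated to
#' zero beyond 1.5 widths from the segment so the ground-truth pixel mask is
#' exact.
#'
#' @param centre Numeric length-2, (x, y) pixel position of the fibre centre.
#' @param length Fibre length in pixels (must exceed `width`).
#' @param width Full width at half maximum in pixels.
#' @param orientation Angle in degrees in `[-90, 90)`; 0 is horizontal,
#'   positive angles rotate towards positive y (downward in image coordinates).
#' @param peak_intensity Peak amplitude added above the image background.
#' @param nmiia_period Spacing in pixels of periodic myosin (NMIIA) puncta
#'   rendered along the fibre in the `nmiia` channel, or `NULL` for none.
#' @return A `fibre_spec` list.
#' @export
fibre_spec <- function(centre, length, width, orientation,
                       peak_intensity = 190, nmiia_period = NULL) {
  stopifnot(length(centre) == 2, length > 0, width > 0)
  if (length <= width) abort("fibre `length` must exceed `width`")
  if (!is.null(nmiia_period) && nmiia_period <= 0) {
    abort("`nmiia_period` must be positive or NULL")
  }
  structure(
    list(centre = as.numeric(centre), length = as.numeric(length),
         width = as.numeric(width),
         orientation = fold_orientation(as.numeric(orientation)),
         peak_intensity = as.numeric(peak_intensity),
         nmiia_period = nmiia_period),
    class = "fibre_spec"
  )
}

#' Describe one synthetic focal adhesion
#'
#' An elliptical punctum with Gaussian profile; `major_axis` and `minor_axis`
#' are the full widths at half maximum along the two principal directions.
#'
#' @param centre (x, y) pixel position.
#' @param major_axis,minor_axis Axis lengths in pixels, `major >= minor > 0`.
#' @param orientation Major-axis angle in degrees.
#' @param peak_intensity Peak amplitude above background.
#' @return An `adhesion_spec` list.
#' @export
adhesion_spec <- function(centre, major_axis, minor_axis, orientation = 0,
                          peak_intensity = 180) {
  stopifnot(length(centre) == 2)
  if (!(major_axis >= minor_axis && minor_axis > 0)) {
    abort("need `major_axis` >= `minor_axis` > 0")
  }
  structure(
    list(centre = as.numeric(centre), major_axis = as.numeric(major_axis),
         minor_axis = as.numeric(minor_axis),
         orientation = fold_orientation(as.numeric(orientation)),
         peak_intensity = as.numeric(peak_intensity)),
    class = "adhesion_spec"
  )
}

#' Describe a synthetic micropatterned cell
#'
#' Defines one multi-channel image of a single cell on an adhesive
#' micropattern: a crossbow (curved leading edge plus a stem), a full disc,
#' or no pattern. Channels are rendered additively as object profiles +
#' uniform background + i.i.d. Gaussian noise, clipped to the bit depth.
#'
#' @param pattern_shape `"crossbow"`, `"disc"` or `"none"`.
#' @param image_size Side of the square image in pixels (>= 64).
#' @param pixel_size Physical pixel size in micrometres per pixel.
#' @param fibres List of [fibre_spec()] objects (rendered in `actin`, and in
#'   `nmiia` as periodic puncta where `nmiia_period` is set).
#' @param adhesions List of [adhesion_spec()] objects (`vinculin` channel).
#' @param n_nuclei Number of round nuclei in the `dapi` channel.
#' @param nucleus_radius Nucleus radius in pixels.
#' @param noise_sd Standard deviation of the additive Gaussian noise.
#' @param background Uniform background intensity.
#' @param bit_depth Bit depth used for clipping (8 or 16).
#' @param seed Integer seed; the same spec and seed give bit-identical images.
#' @return A `cell_spec` list.
#' @export
cell_spec <- function(pattern_shape = c("crossbow", "disc", "none"),
                      image_size = 256, pixel_size = 0.2,
                      fibres = list(), adhesions = list(),
                      n_nuclei = 1, nucleus_radius = 16,
                      noise_sd = 5, background = 10,
                      bit_depth = 8, seed = 1) {
  pattern_shape <- match.arg(pattern_shape)
  if (image_size < 64) abort("`image_size` must be at least 64")
  if (pixel_size <= 0) abort("`pixel_size` must be positive")
  if (noise_sd < 0) abort("`noise_sd` must be non-negative")
  if (n_nuclei < 0) abort("`n_nuclei` must be non-negative")
  for (f in fibres) {
    if (!inherits(f, "fibre_spec")) abort("`fibres` must contain fibre_spec objects")
    if (f$peak_intensity <= 0) abort("fibre peak intensity must exceed the background")
  }
  for (a in adhesions) {
    if (!inherits(a, "adhesion_spec")) abort("`adhesions` must contain adhesion_spec objects")
  }
  structure(
    list(pattern_shape = pattern_shape, image_size = as.integer(image_size),
         pixel_size = pixel_size, fibres = fibres, adhesions = adhesions,
         n_nuclei = as.integer(n_nuclei), nucleus_radius = nucleus_radius,
         noise_sd = noise_sd, background = background,
         bit_depth = as.integer(bit_depth), seed = as.integer(seed)),
    class = "cell_spec"
  )
}

#' Crossbow micropattern geometry and mask
#'
#' The crossbow is a circular arc (the curved leading edge) plus a straight
#' stem from the arc's centre of curvature downward. Commercial micropattern
#' geometries are proprietary, so this parametric arc-and-stem is the
#' package's reference geometry; edge-distance measurements are defined
#' against it.
#'
#' @param image_size Side of the square image in pixels.
#' @param radius Arc radius in pixels (default one third of the image).
#' @param stroke Stroke width of the printed pattern in pixels.
#' @param theta_span Total angular span of the arc in degrees, centred on the
#'   top of the image.
#' @return List with `geometry` (centre, radius, theta range in degrees,
#'   stroke) and `mask` (logical matrix of the printed pattern).
#' @export
crossbow_pattern <- function(image_size = 256, radius = round(image_size / 3),
                             stroke = max(3, round(image_size / 50)),
                             theta_span = 220) {
  cx <- (image_size + 1) / 2
  cy <- (image_size + 1) / 2
  t0 <- 90 - theta_span / 2
  t1 <- 90 + theta_span / 2
  g <- coord_grid(image_size, image_size)
  r <- sqrt((g$x - cx)^2 + (g$y - cy)^2)
  # angle measured anticlockwise from +x with y pointing up (image top = 90 deg)
  phi <- atan2(cy - g$y, g$x - cx) * 180 / pi
  in_span <- ((phi - t0) %% 360) <= (t1 - t0)
  arc <- abs(r - radius) <= stroke / 2 & in_span
  stem <- abs(g$x - cx) <= stroke / 2 & g$y >= cy & g$y <= cy + radius
  list(
    geometry = list(centre = c(cx, cy), radius = radius,
                    theta_start = t0, theta_end = t1, stroke = stroke),
    mask = arc | stem
  )
}

# Render a straight fibre with Gaussian cross-section; returns the intensity
# contribution (amplitude 1) and the exact support mask.
render_fibre <- function(nx, ny, centre, len, width, orientation) {
  th <- orientation * pi / 180
  u <- c(cos(th), sin(th))
  sigma <- width / 2.355
  reach_long <- len / 2
  reach_perp <- 1.5 * width
  half_x <- reach_long * abs(u[1]) + reach_perp * abs(u[2])
  half_y <- reach_long * abs(u[2]) + reach_perp * abs(u[1])
  if (centre[1] - half_x < 1 || centre[1] + half_x > nx ||
      centre[2] - half_y < 1 || centre[2] + half_y > ny) {
    abort("fibre support extends outside the image: placement error")
  }
  g <- coord_grid(nx, ny)
  rx <- g$x - centre[1]; ry <- g$y - centre[2]
  s <- rx * u[1] + ry * u[2]
  d <- -rx * u[2] + ry * u[1]
  # sharp end caps: apparent length does not depend on the threshold level
  amp <- exp(-d^2 / (2 * sigma^2))
  support <- abs(d) <= reach_perp & abs(s) <= reach_long
  amp[!support] <- 0
  core <- abs(d) <= width / 2 & abs(s) <= reach_long
  list(profile = amp, mask = which(support), core = which(core))
}

render_ellipse <- function(nx, ny, centre, major, minor, orientation) {
  th <- orientation * pi / 180
  u <- c(cos(th), sin(th))
  sa <- major / 2.355; sb <- minor / 2.355
  reach_a <- 1.5 * major; reach_b <- 1.5 * minor
  half_x <- reach_a * abs(u[1]) + reach_b * abs(u[2])
  half_y <- reach_a * abs(u[2]) + reach_b * abs(u[1])
  if (centre[1] - half_x < 1 || centre[1] + half_x > nx ||
      centre[2] - half_y < 1 || centre[2] + half_y > ny) {
    abort("adhesion support extends outside the image: placement error")
  }
  g <- coord_grid(nx, ny)
  rx <- g$x - centre[1]; ry <- g$y - centre[2]
  s <- rx * u[1] + ry * u[2]
  d <- -rx * u[2] + ry * u[1]
  amp <- exp(-(s^2 / (2 * sa^2) + d^2 / (2 * sb^2)))
  support <- (s / reach_a)^2 + (d / reach_b)^2 <= 1
  amp[!support] <- 0
  core <- (s / (major / 2))^2 + (d / (minor / 2))^2 <= 1
  list(profile = amp, mask = which(support), core = which(core))
}

# Round nucleus: flat top with a Gaussian rim rolloff of sd 1 px.
render_nucleus <- function(nx, ny, centre, radius) {
  if (centre[1] - radius - 3 < 1 || centre[1] + radius + 3 > nx ||
      centre[2] - radius - 3 < 1 || centre[2] + radius + 3 > ny) {
    abort("nucleus support extends outside the image: placement error")
  }
  g <- coord_grid(nx, ny)
  r <- sqrt((g$x - centre[1])^2 + (g$y - centre[2])^2)
  amp <- ifelse(r <= radius, 1, exp(-(r - radius)^2 / 2))
  support <- r <= radius + 3
  amp[!support] <- 0
  list(profile = amp, mask = which(support), core = which(r <= radius))
}

render_spot <- function(nx, ny, centre, sigma) {
  g <- coord_grid(nx, ny)
  r2 <- (g$x - centre[1])^2 + (g$y - centre[2])^2
  reach2 <- (4 * sigma)^2
  amp <- exp(-r2 / (2 * sigma^2))
  amp[r2 > reach2] <- 0
  list(profile = amp, mask = which(r2 <= reach2))
}

#' Generate a synthetic micropatterned cell image with ground truth
#'
#' Renders every channel described by the spec additively (object profiles +
#' uniform background + Gaussian noise of sd `noise_sd`), clipped to the bit
#' depth. Channels produced: `pattern` (the printed micropattern), `actin`
#' (fibres), `vinculin` (adhesions, if any), `dapi` (nuclei), and `nmiia`
#' (periodic puncta along fibres that declare a period).
#'
#' @param spec A [cell_spec()].
#' @return List with `channels` (named list of matrices) and `truth`, a
#'   `ground_truth` object carrying the spec echo, per-object parameter
#'   tables, exact per-object pixel masks, the pattern geometry and summary
#'   counts.
#' @export
generate_micropattern_cell <- function(spec) {
  stopifnot(inherits(spec, "cell_spec"))
  n <- spec$image_size
  bg <- spec$background
  maxv <- 2^spec$bit_depth - 1

  with_seed(spec$seed, {
    pattern <- switch(spec$pattern_shape,
      crossbow = crossbow_pattern(n),
      disc = {
        g <- coord_grid(n, n)
        r <- sqrt((g$x - (n + 1) / 2)^2 + (g$y - (n + 1) / 2)^2)
        list(geometry = list(centre = c((n + 1) / 2, (n + 1) / 2),
                             radius = round(n / 3)),
             mask = r <= round(n / 3))
      },
      none = list(geometry = NULL, mask = matrix(FALSE, n, n))
    )

    channels <- list()
    masks <- list()
    core_masks <- list()
    channels$pattern <- pattern$mask * 120

    actin <- matrix(0, n, n)
    nmiia <- matrix(0, n, n)
    fib_rows <- list()
    any_nmiia <- FALSE
    for (i in seq_along(spec$fibres)) {
      f <- spec$fibres[[i]]
      rf <- render_fibre(n, n, f$centre, f$length, f$width, f$orientation)
      actin <- actin + f$peak_intensity * rf$profile
      masks[[paste0("fibre_", i)]] <- rf$mask
      core_masks[[paste0("fibre_", i)]] <- rf$core
      if (!is.null(f$nmiia_period)) {
        any_nmiia <- TRUE
        th <- f$orientation * pi / 180
        u <- c(cos(th), sin(th))
        half <- f$length / 2
        pos <- seq(-half + f$nmiia_period / 2, half, by = f$nmiia_period)
        for (s in pos) {
          sp <- render_spot(n, n, f$centre + s * u, f$width / 2.355)
          nmiia <- nmiia + f$peak_intensity * sp$profile
        }
      }
      fib_rows[[i]] <- tibble::tibble(
        id = i, x = f$centre[1], y = f$centre[2], length = f$length,
        width = f$width, orientation = f$orientation,
        peak_intensity = f$peak_intensity,
        nmiia_period = if (is.null(f$nmiia_period)) NA_real_ else f$nmiia_period
      )
    }
    fib_tb <- if (length(fib_rows)) dplyr::bind_rows(fib_rows) else NULL
    channels$actin <- actin
    if (any_nmiia) channels$nmiia <- nmiia

    adh_rows <- list()
    if (length(spec$adhesions)) {
      vinc <- matrix(0, n, n)
      for (i in seq_along(spec$adhesions)) {
        a <- spec$adhesions[[i]]
        re <- render_ellipse(n, n, a$centre, a$major_axis, a$minor_axis,
                             a$orientation)
        vinc <- vinc + a$peak_intensity * re$profile
        masks[[paste0("adhesion_", i)]] <- re$mask
        core_masks[[paste0("adhesion_", i)]] <- re$core
        adh_rows[[i]] <- tibble::tibble(
          id = i, x = a$centre[1], y = a$centre[2],
          major_axis = a$major_axis, minor_axis = a$minor_axis,
          orientation = a$orientation, peak_intensity = a$peak_intensity)
      }
      channels$vinculin <- vinc
    }
    adh_tb <- if (length(adh_rows)) dplyr::bind_rows(adh_rows) else NULL

    nuc_tb <- NULL
    dapi <- matrix(0, n, n)
    if (spec$n_nuclei > 0) {
      rad <- spec$nucleus_radius
      centres <- place_points(spec$n_nuclei, min_sep = 2.4 * rad,
                              lo = rad + 4, hi = n - rad - 4)
      nuc_rows <- list()
      for (i in seq_along(centres)) {
        p <- centres[[i]]
        rn <- render_nucleus(n, n, p, rad)
        dapi <- dapi + 200 * rn$profile
        masks[[paste0("nucleus_", i)]] <- rn$mask
        core_masks[[paste0("nucleus_", i)]] <- rn$core
        nuc_rows[[i]] <- tibble::tibble(id = i, x = p[1], y = p[2], radius = rad)
      }
      nuc_tb <- dplyr::bind_rows(nuc_rows)
    }
    channels$dapi <- dapi

    channels <- lapply(channels, function(ch) {
      out <- ch + bg
      if (spec$noise_sd > 0) out <- out + rnorm(length(out), 0, spec$noise_sd)
      clip_intensity(matrix(out, n, n), spec$bit_depth)
    })

    truth <- structure(
      list(spec = spec, fibres = fib_tb, adhesions = adh_tb, nuclei = nuc_tb,
           masks = masks, core_masks = core_masks,
           pattern_geometry = pattern$geometry,
           pattern_mask = pattern$mask,
           summaries = list(n_fibres = length(spec$fibres),
                            n_adhesions = length(spec$adhesions),
                            n_nuclei = spec$n_nuclei)),
      class = "ground_truth"
    )
    list(channels = channels, truth = truth)
  })
}

# Rejection-sample k points in [lo, hi]^2 with pairwise separation >= min_sep.
place_points <- function(k, min_sep, lo, hi, max_tries = 20000) {
  if (k == 0) return(list())
  if (hi <= lo) abort("no room to place objects: placement error")
  pts <- matrix(NA_real_, 0, 2)
  tries <- 0
  while (nrow(pts) < k) {
    tries <- tries + 1
    if (tries > max_tries) {
      abort("cannot place requested objects at the requested separation: placement error")
    }
    p <- runif(2, lo, hi)
    if (nrow(pts) == 0 ||
        all(sqrt((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2) >= min_sep)) {
      pts <- rbind(pts, p)
    }
  }
  lapply(seq_len(k), function(i) pts[i, ])
}

#' Generate a synthetic proximity-ligation (PLA) foci image
#'
#' Round Gaussian spots at random, well-separated positions on a uniform
#' background, mimicking discrete PLA signals. The minimum separation must
#' exceed four spot sigmas so every spot is resolvable by construction.
#'
#' @param n_foci Number of spots (>= 0).
#' @param min_separation Minimum pairwise centre distance in pixels.
#' @param spot_sigma Gaussian sigma of one spot in pixels.
#' @param noise_sd Additive Gaussian noise sd.
#' @param seed Integer seed.
#' @param image_size Side of the square image.
#' @param background Uniform background level.
#' @param peak_intensity Spot amplitude above background.
#' @return List with `image` (matrix) and `truth` (`ground_truth` with a
#'   `foci` tibble of centres).
#' @export
generate_foci_image <- function(n_foci, min_separation = 12, spot_sigma = 1.5,
                                noise_sd = 2, seed = 1, image_size = 256,
                                background = 10, peak_intensity = 150) {
  if (n_foci < 0) abort("`n_foci` must be non-negative")
  if (min_separation <= 4 * spot_sigma) {
    abort("`min_separation` must exceed 4 * `spot_sigma`")
  }
  with_seed(seed, {
    n <- image_size
    margin <- 4 * spot_sigma + 2
    img <- matrix(background, n, n)
    centres <- place_points(n_foci, min_sep = min_separation,
                            lo = margin, hi = n - margin)
    masks <- list()
    for (i in seq_along(centres)) {
      sp <- render_spot(n, n, centres[[i]], spot_sigma)
      img <- img + peak_intensity * sp$profile
      masks[[paste0("focus_", i)]] <- sp$mask
    }
    if (noise_sd > 0) {
      img <- img + matrix(rnorm(n * n, 0, noise_sd), n, n)
    }
    img <- clip_intensity(img, 8)
    foci_tb <- if (n_foci > 0) {
      tibble::tibble(
        id = seq_len(n_foci),
        x = vapply(centres, `[`, numeric(1), 1),
        y = vapply(centres, `[`, numeric(1), 2)
      )
    } else {
      tibble::tibble(id = integer(), x = numeric(), y = numeric())
    }
    truth <- structure(
      list(spec = list(n_foci = n_foci, min_separation = min_separation,
                       spot_sigma = spot_sigma, noise_sd = noise_sd,
                       seed = seed, image_size = image_size,
                       background = background,
                       peak_intensity = peak_intensity),
           foci = foci_tb, masks = masks,
           summaries = list(n_foci = n_foci)),
      class = "ground_truth"
    )
    list(image = img, truth = truth)
  })
}

#' Describe a synthetic scratch-wound time lapse
#'
#' A vertical cell-free band of declared initial width closes symmetrically
#' at a constant per-front edge velocity; the true width at frame k
#' (0-based) is `max(0, initial_width - 2 * edge_velocity * k * dt)`.
#' Cell-covered regions carry i.i.d. texture, the wound is near background.
#'
#' @param frame_size Side of the square frame in pixels.
#' @param pixel_size Micrometres per pixel.
#' @param initial_width Initial wound width in micrometres.
#' @param edge_velocity Per-front edge speed in micrometres per hour.
#' @param dt Hours between frames.
#' @param n_frames Number of frames.
#' @param texture_sd Intensity sd of the cell-region texture.
#' @param cell_intensity Mean intensity of the cell-covered region.
#' @param background Background intensity (wound region).
#' @param seed Integer seed.
#' @return A `wound_spec` list.
#' @export
wound_spec <- function(frame_size = 400, pixel_size = 2, initial_width = 500,
                       edge_velocity = 10, dt = 1, n_frames = 21,
                       texture_sd = 12, cell_intensity = 110,
                       background = 10, seed = 1) {
  if (initial_width <= 0) abort("`initial_width` must be positive")
  if (edge_velocity < 0) abort("`edge_velocity` must be non-negative")
  if (dt <= 0 || n_frames < 1) abort("need `dt` > 0 and `n_frames` >= 1")
  structure(
    list(frame_size = as.integer(frame_size), pixel_size = pixel_size,
         initial_width = initial_width, edge_velocity = edge_velocity,
         dt = dt, n_frames = as.integer(n_frames), texture_sd = texture_sd,
         cell_intensity = cell_intensity, background = background,
         seed = as.integer(seed)),
    class = "wound_spec"
  )
}

#' Generate a synthetic wound-healing time lapse with ground truth
#'
#' @param spec A [wound_spec()].
#' @return List with `frames` (list of matrices, one per time point) and
#'   `truth` (`ground_truth` whose `frames` tibble holds the true time,
#'   width and area of the wound at every frame).
#' @export
generate_wound_series <- function(spec) {
  stopifnot(inherits(spec, "wound_spec"))
  with_seed(spec$seed, {
    n <- spec$frame_size
    cx <- (n + 1) / 2
    ks <- seq_len(spec$n_frames) - 1
    widths_um <- pmax(0, spec$initial_width - 2 * spec$edge_velocity * ks * spec$dt)
    height_um <- n * spec$pixel_size
    xs <- seq_len(n)
    frames <- lapply(seq_along(ks), function(i) {
      half_px <- widths_um[i] / (2 * spec$pixel_size)
      wound_cols <- abs(xs - cx) <= half_px
      img <- matrix(spec$background, n, n)
      img <- img + matrix(rnorm(n * n, 0, spec$texture_sd * 0.05), n, n)
      ncell <- sum(!wound_cols) * n
      if (ncell > 0) {
        cell <- matrix(spec$cell_intensity +
                         rnorm(ncell, 0, spec$texture_sd),
                       nrow = sum(!wound_cols))
        img[!wound_cols, ] <- cell
      }
      clip_intensity(img, 8)
    })
    truth <- structure(
      list(spec = spec,
           frames = tibble::tibble(
             frame = seq_along(ks),
             t = ks * spec$dt,
             width_um = widths_um,
             area_um2 = widths_um * height_um
           ),
           summaries = list(n_frames = spec$n_frames,
                            closes_at = if (any(widths_um == 0))
                              min(which(widths_um == 0)) else NA_integer_)),
      class = "ground_truth"
    )
    list(frames = frames, truth = truth)
  })
}
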