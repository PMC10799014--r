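#' Plot a frequency map
#'
#' Renders the 0–255 reference-cell map as a raster with a perceptually
#' ordered colour scale (the modern stand-in for the rainbow LUT of the
#' original macro).
#'
#' @param object A `frequency_map`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot frequency_map
#' @export
autoplot.frequency_map <- function(object, ...) {
  df <- tibble::tibble(
    x = as.vector(row(object$map)),
    y = as.vector(col(object$map)),
    intensity = as.vector(object$map)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 255), option = "turbo") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("Frequency map: %s (n = %d)",
                                  object$channel, object$n_cells),
                  fill = "0-255") +
    ggplot2::theme_minimal()
}

#' Plot an orientation histogram
#'
#' @param object An `orientation_histogram`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot orientation_histogram
#' @export
autoplot.orientation_histogram <- function(object, ...) {
  ggplot2::ggplot(object$hist,
                  ggplot2::aes(.data$bin_mid, .data$weight)) +
    ggplot2::geom_col(width = diff(object$hist$bin_left[1:2]) * 0.9) +
    ggplot2::labs(x = "orientation (deg)", y = "gradient energy",
                  title = sprintf("Mean %.1f deg, coherence %.2f",
                                  object$mean_deg, object$coherence)) +
    ggplot2::theme_minimal()
}

#' Plot filament records as a spatial map
#'
#' Scatter of filament centres coloured by width — the thick-filament map
#' once filtered with [thick_object_map()].
#'
#' @param object A `filament_set` (or `adhesion_set`) tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot filament_set
#' @export
autoplot.filament_set <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$x, .data$y, colour = .data$width_um)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_colour_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(colour = "width (um)") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.filament_set
#' @method autoplot adhesion_set
#' @export
autoplot.adhesion_set <- autoplot.filament_set

#' Plot wound kinetics
#'
#' Wound width and closure percentage against time.
#'
#' @param object A `wound_kinetics` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot wound_kinetics
#' @export
autoplot.wound_kinetics <- function(object, ...) {
  df <- tidyr::pivot_longer(object$curve,
                            c("width_um", "closure_pct"),
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$t, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~metric, scales = "free_y",
                        labeller = ggplot2::as_labeller(
                          c(width_um = "wound width (um)",
                            closure_pct = "closure (%)"))) +
    ggplot2::labs(x = "time (h)", y = NULL,
                  title = sprintf("Migration rate %.1f um/h",
                                  object$migration_rate_um_h)) +
    ggplot2::theme_minimal()
}

#' Plot a line profile with its detected peaks
#'
#' @param object A `line_profile`.
#' @param peaks Optional `peak_set` from [find_peaks()] to overlay.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot line_profile
#' @export
autoplot.line_profile <- function(object, peaks = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$position, .data$intensity)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "position (px)", y = "intensity") +
    ggplot2::theme_minimal()
  if (!is.null(peaks) && nrow(peaks) > 0) {
    p <- p + ggplot2::geom_point(data = peaks, colour = "red", size = 2)
  }
  p
}
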