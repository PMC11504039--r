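#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_raster
#'   geom_path facet_wrap labs scale_fill_gradient theme_minimal
NULL

#' @export
ggplot2::autoplot

#' Plot a pressure/flow waveform
#'
#' Pressures (ventricular and aortic) and transaortic flow in stacked
#' facets.
#'
#' @param object A `pf_waveform`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pf_waveform <- function(object, ...) {
  long <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(-"time_s", names_to = "channel") |>
    dplyr::mutate(panel = ifelse(.data$channel == "q_mls",
                                 "flow (mL/s)", "pressure (mmHg)"))
  ggplot(long, aes(.data$time_s, .data$value, colour = .data$channel)) +
    geom_line() +
    facet_wrap(~panel, ncol = 1, scales = "free_y") +
    labs(x = "time (s)", y = NULL, colour = NULL) +
    theme_minimal()
}

#' Plot a Hertzian contact fit
#'
#' Observed loading-segment load-displacement samples with the fitted
#' Hertz curve overlaid.
#'
#' @param object A `hertz_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hertz_fit <- function(object, ...) {
  ggplot(object$data, aes(.data$displacement_um, .data$load_uN)) +
    geom_point(alpha = 0.5, size = 0.8) +
    geom_line(aes(y = .data$fitted_uN), colour = "firebrick") +
    labs(x = "indentation depth (µm)", y = "load (µN)",
         title = sprintf("E = %.1f kPa", object$youngs_modulus_kPa)) +
    theme_minimal()
}

#' Plot per-node leaflet hemodynamics against radial position
#'
#' TAWSS and OSI per node versus the node's distance from the leaflet
#' centre (belly), the axis along which the shear pattern varies.
#'
#' @param summary A `hemodynamic_summary` (from
#'   [summarize_hemodynamics()]).
#' @param field The `wss_field` the summary came from (for node radii).
#' @return A ggplot.
#' @export
plot_hemodynamics <- function(summary, field) {
  r <- sqrt(field$nodes$x^2 + field$nodes$y^2)
  d <- summary$per_node |>
    dplyr::mutate(radius = r[.data$node]) |>
    tidyr::pivot_longer(c("tawss", "osi"), names_to = "quantity")
  ggplot(d, aes(.data$radius, .data$value)) +
    geom_point(alpha = 0.6) +
    facet_wrap(~quantity, scales = "free_y") +
    labs(x = "radial position (belly → free edge)", y = NULL) +
    theme_minimal()
}

#' Plot a valve frame with the measured orifice contour overlaid
#'
#' @param frame An [orifice_frame()].
#' @param goa A `goa_result` from [compute_goa()] or [measure_goa()].
#' @return A ggplot mirroring the usual planimetry overlay (contour drawn
#'   over the grayscale frame).
#' @export
plot_goa_overlay <- function(frame, goa) {
  px <- frame$pixels
  d <- tibble::tibble(row = rep(seq_len(nrow(px)), times = ncol(px)),
                      col = rep(seq_len(ncol(px)), each = nrow(px)),
                      value = as.vector(px))
  ggplot(d, aes(.data$col, .data$row, fill = .data$value)) +
    geom_raster() +
    scale_fill_gradient(low = "black", high = "white", guide = "none") +
    geom_path(data = goa$contour, aes(.data$col, .data$row),
              inherit.aes = FALSE, colour = "red", linewidth = 0.7) +
    labs(x = NULL, y = NULL,
         title = sprintf("GOA = %.2f cm²", goa$area_cm2)) +
    theme_minimal()
}
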