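#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Dose-response plot of quantified lanes
#'
#' Events per Mbp against dose, one panel per metric, coloured by enzyme
#' treatment — the plot whose slopes are the G-values.
#'
#' @param quantified Output of [quantify_lanes()].
#' @return A ggplot.
#' @export
plot_dose_response <- function(quantified) {
  q <- tibble::as_tibble(quantified)
  if (!"enzyme" %in% names(q)) q$enzyme <- "none"
  long <- tidyr::pivot_longer(
    q[, c("dose_gy", "enzyme", "ssb_mbp", "dsb_mbp")],
    cols = c("ssb_mbp", "dsb_mbp"),
    names_to = "metric", values_to = "events_per_mbp"
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$dose_gy, .data$events_per_mbp,
                                     colour = .data$enzyme)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.5) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "dose (Gy)", y = expression(events ~ Mbp^-1)) +
    ggplot2::theme_minimal()
}

#' Yield versus scavenging capacity
#'
#' Log-capacity plot of damage yields, the standard presentation of
#' radical-scavenging experiments.
#'
#' @param yields_by_capacity Data frame with `capacity_s`, `metric`,
#'   `g_value` and optionally `sem` and `scavenger`.
#' @return A ggplot.
#' @export
plot_protection <- function(yields_by_capacity) {
  y <- tibble::as_tibble(yields_by_capacity)
  p <- ggplot2::ggplot(y, ggplot2::aes(.data$capacity_s, .data$g_value))
  if ("scavenger" %in% names(y)) {
    p <- p + ggplot2::aes(colour = .data$scavenger)
  }
  p <- p + ggplot2::geom_point() + ggplot2::geom_line()
  if ("sem" %in% names(y)) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$g_value - .data$sem,
                   ymax = .data$g_value + .data$sem),
      width = 0.05
    )
  }
  p +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = expression(scavenging ~ capacity ~ (s^-1)),
                  y = expression(G ~ (events ~ Mbp^-1 ~ Gy^-1))) +
    ggplot2::theme_minimal()
}

#' Plot an AFM height map
#'
#' @param object An [afm_image()].
#' @param ... Unused.
#' @return A ggplot raster of the height field.
#' @export
autoplot.afm_image <- function(object, ...) {
  df <- expand.grid(
    x_nm = (seq_len(object$pixels_x) - 0.5) * object$nm_per_px,
    y_nm = (seq_len(object$pixels_y) - 0.5) * object$nm_per_px
  )
  df$height_nm <- as.vector(t(object$heights))
  ggplot2::ggplot(df, ggplot2::aes(.data$x_nm, .data$y_nm,
                                   fill = .data$height_nm)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "height (nm)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (nm)", y = "y (nm)") +
    ggplot2::theme_minimal()
}
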