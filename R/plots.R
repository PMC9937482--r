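# ggplot2 visualisations of the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an equirectangular heatmap
#'
#' @param object a `pg_heatmap`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.pg_heatmap <- function(object, ...) {
  df <- tibble::tibble(
    lon = rep(attr(object, "lon_centers"), each = nrow(object)),
    lat = rep(attr(object, "lat_centers"), times = ncol(object)),
    density = as.vector(unclass(object)))
  ggplot2::ggplot(df, ggplot2::aes(.data$lon, .data$lat, fill = .data$density)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed(xlim = c(-180, 180), ylim = c(-90, 90), expand = FALSE) +
    ggplot2::labs(x = "longitude (deg)", y = "latitude (deg)", fill = "density")
}

#' Plot a cross-recurrence diagram
#'
#' @param object a `pg_recurrence` matrix.
#' @param ... unused.
#' @return a ggplot with encoding fixation index on the vertical axis and
#'   recognition index on the horizontal.
#' @export
autoplot.pg_recurrence <- function(object, ...) {
  ij <- which(unclass(object) == 1L, arr.ind = TRUE)
  df <- tibble::tibble(encoding = ij[, 1], recognition = ij[, 2])
  ggplot2::ggplot(df, ggplot2::aes(.data$recognition, .data$encoding)) +
    ggplot2::geom_point(shape = 15, size = 2) +
    ggplot2::coord_fixed(xlim = c(0.5, ncol(object) + 0.5),
                         ylim = c(0.5, nrow(object) + 0.5), expand = FALSE) +
    ggplot2::labs(x = "recognition fixation", y = "encoding fixation",
                  subtitle = sprintf("radius %.2f deg", attr(object, "radius")))
}

#' Plot a gaze series on the sphere map
#'
#' Eye (and optionally head) traces over the equirectangular map, with
#' fixation centroids overlaid when supplied.
#'
#' @param gaze a `pg_gaze` tibble.
#' @param fixations optional `pg_fixations` tibble.
#' @param head logical; draw the head-point trace too.
#' @return a ggplot.
#' @export
plot_gaze <- function(gaze, fixations = NULL, head = TRUE) {
  p <- ggplot2::ggplot(gaze, ggplot2::aes(.data$eye_lon, .data$eye_lat)) +
    ggplot2::geom_path(alpha = 0.4, colour = "steelblue") +
    ggplot2::coord_fixed(xlim = c(-180, 180), ylim = c(-90, 90), expand = FALSE) +
    ggplot2::labs(x = "longitude (deg)", y = "latitude (deg)")
  if (head) {
    p <- p + ggplot2::geom_path(ggplot2::aes(.data$head_lon, .data$head_lat),
                                alpha = 0.4, colour = "firebrick")
  }
  if (!is.null(fixations) && nrow(fixations)) {
    p <- p + ggplot2::geom_point(data = fixations,
                                 ggplot2::aes(.data$lon, .data$lat,
                                              size = .data$duration),
                                 inherit.aes = FALSE, alpha = 0.7)
  }
  p
}

#' Plot condition-level CRA summaries
#'
#' One panel per measure, conditions on the horizontal axis, separate colours
#' for eye and head targets.
#'
#' @param cra_summary a `pg_cra_summary` (from [run_condition_cra()]).
#' @return a ggplot.
#' @export
plot_cra_summary <- function(cra_summary) {
  s <- cra_summary$summary
  s$condition <- factor(s$condition, c("Sp-Si", "Sp-Di", "Dp-Si", "Dp-Di"))
  ggplot2::ggplot(s, ggplot2::aes(.data$condition, .data$mean,
                                  fill = .data$target)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd / sqrt(.data$n),
                                        ymax = .data$mean + .data$sd / sqrt(.data$n)),
                           position = ggplot2::position_dodge(0.9), width = 0.3) +
    ggplot2::facet_wrap(~ measure, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "mean across participants", fill = NULL)
}
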