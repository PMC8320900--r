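# ggplot2 visualisations: network maps in the reference colour code (corner
# red, septal blue, distribution green) and log-scale perfusion intensity maps.

vessel_kind_colors <- c(corner = "#d62728", septal = "#1f77b4", distribution = "#2ca02c")

#' Plot an ACU network
#'
#' @param object An `acu_network`.
#' @param ... Unused.
#' @return A ggplot: edges coloured by vessel kind, inlet/outlet nodes marked.
#' @method autoplot acu_network
#' @export
autoplot.acu_network <- function(object, ...) {
  ed <- tidy(object)
  nd <- object$nodes
  acc <- nd[nd$id %in% c(object$inlets, object$outlets), , drop = FALSE]
  acc$role <- if_else(acc$id %in% object$inlets, "inlet", "outlet")
  ggplot(ed) +
    geom_segment(aes(x = .data$x0, y = .data$y0, xend = .data$x1, yend = .data$y1,
                     color = .data$kind, linewidth = .data$diameter_um)) +
    geom_point(data = acc, aes(x = .data$x_um, y = .data$y_um, shape = .data$role),
               size = 3, stroke = 1.2) +
    ggplot2::scale_linewidth_continuous(range = c(0.2, 2), guide = "none") +
    scale_color_manual(values = vessel_kind_colors) +
    scale_y_reverse() + coord_equal() + theme_minimal() +
    labs(x = "x (μm)", y = "y (μm)", color = "vessel", shape = NULL)
}

#' Plot a perfusion solution as a log-scale flow map
#'
#' @param object An `acu_perfusion`.
#' @param ... Unused.
#' @return A ggplot: patent edges coloured by log10 |flow|, closed edges grey.
#' @method autoplot acu_perfusion
#' @export
autoplot.acu_perfusion <- function(object, ...) {
  net <- object$network
  ed <- tidy(net) |>
    left_join(object$edges |> select("id", "patent", "flow_m3s"), by = "id")
  qmax <- max(abs(ed$flow_m3s), na.rm = TRUE)
  ed$logq <- log10(pmax(abs(ed$flow_m3s), qmax * 1e-6))
  open <- ed[ed$patent & abs(ed$flow_m3s) > 0, ]
  shut <- ed[!ed$patent | abs(ed$flow_m3s) == 0, ]
  p <- ggplot() +
    geom_segment(data = shut, aes(x = .data$x0, y = .data$y0, xend = .data$x1, yend = .data$y1),
                 color = "grey80", linewidth = 0.3)
  if (nrow(open) > 0) {
    p <- p + geom_segment(
      data = open,
      aes(x = .data$x0, y = .data$y0, xend = .data$x1, yend = .data$y1, color = .data$logq),
      linewidth = 0.8) +
      ggplot2::scale_color_viridis_c(name = "log10 |Q| (m³/s)")
  }
  p + scale_y_reverse() + coord_equal() + theme_minimal() +
    labs(title = object$bc$label, x = "x (μm)", y = "y (μm)")
}

#' Plot a micro image
#'
#' @param object A `micro_image`.
#' @param ... Unused.
#' @return A ggplot raster in physical (μm) coordinates.
#' @method autoplot micro_image
#' @export
autoplot.micro_image <- function(object, ...) {
  df <- expand.grid(row = seq_len(nrow(object$pixels)), col = seq_len(ncol(object$pixels)))
  df$grey <- as.vector(object$pixels)
  df$x <- (df$col - 0.5) * object$pixel_scale
  df$y <- (df$row - 0.5) * object$pixel_scale
  ggplot(df, aes(x = .data$x, y = .data$y, fill = .data$grey)) +
    geom_raster() +
    scale_fill_gradient(low = "black", high = "white", limits = c(0, 255)) +
    scale_y_reverse() + coord_equal() + theme_minimal() +
    labs(x = "x (μm)", y = "y (μm)", fill = "grey")
}

#' Plot study report time-courses
#'
#' @param study An `acu_study` from [run_study()].
#' @param quantity Column of the report to draw.
#' @return A ggplot of the quantity per ACU across timepoints.
#' @export
plot_study <- function(study, quantity = "jv_per_surface_1e10_ms") {
  stopifnot(inherits(study, "acu_study"))
  ggplot(study$report,
         aes(x = .data$timepoint_min, y = .data[[quantity]],
             color = .data$acu, group = .data$acu)) +
    ggplot2::geom_line() + geom_point(size = 2) + theme_minimal() +
    labs(x = "time (min)", y = quantity, color = NULL)
}
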