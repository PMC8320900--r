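# broom-style tidiers: tidy() returns a per-element tibble, glance() a one-row
# summary, for each result type.

#' @method tidy acu_network
#' @export
tidy.acu_network <- function(x, ...) {
  pos <- x$nodes
  x$edges |>
    left_join(pos |> select(from = "id", x0 = "x_um", y0 = "y_um"), by = "from") |>
    left_join(pos |> select(to = "id", x1 = "x_um", y1 = "y_um"), by = "to")
}

#' @method glance acu_network
#' @export
glance.acu_network <- function(x, ...) {
  has_sep <- any(x$edges$kind == "septal")
  mcl <- if (any(x$edges$kind == "corner")) mean_corner_length(x) else
    tibble(n_corner = 0L, mean_um = NA_real_, sd_um = NA_real_)
  tibble(
    n_nodes = nrow(x$nodes),
    n_edges = nrow(x$edges),
    n_septal = sum(x$edges$kind == "septal"),
    n_corner = mcl$n_corner,
    mean_corner_length_um = mcl$mean_um,
    sd_corner_length_um = mcl$sd_um,
    polygon_area_um2 = if (!is.null(x$polygon)) polygon_area(x$polygon) else NA_real_,
    capillary_volume_um3 = capillary_volume(x),
    volume_ratio = if (has_sep && !is.null(x$polygon)) volume_ratio(x) else NA_real_
  )
}

#' @method tidy acu_perfusion
#' @export
tidy.acu_perfusion <- function(x, ...) x$edges

#' @method glance acu_perfusion
#' @export
glance.acu_perfusion <- function(x, ...) {
  tibble(
    label = x$bc$label,
    acu_flow_m3s = x$acu_flow_m3s,
    corner_flow_m3s = x$corner_flow_m3s,
    septal_flow_m3s = x$septal_flow_m3s,
    septal_to_corner_ratio = x$septal_to_corner_ratio,
    n_septal_patent = sum(x$edges$patent[x$edges$kind == "septal"]),
    n_septal = sum(x$edges$kind == "septal"),
    fully_derecruited = x$fully_derecruited,
    iterations = x$iterations
  )
}

#' @method tidy acu_filtration
#' @export
tidy.acu_filtration <- function(x, ...) x$edges

#' @method glance acu_filtration
#' @export
glance.acu_filtration <- function(x, ...) {
  tibble(
    label = x$bc$label,
    surface_m2 = x$surface_m2,
    jv_m3s = x$jv_m3s,
    jv_per_surface_ms = x$jv_per_surface_ms,
    pct_surface = x$pct_surface,
    pct_jv = x$pct_jv,
    pct_jv_per_surface = x$pct_jv_per_surface
  )
}

#' @method tidy acu_study
#' @export
tidy.acu_study <- function(x, ...) x$report

#' @method glance acu_study
#' @export
glance.acu_study <- function(x, ...) {
  x$report |>
    group_by(.data$acu) |>
    summarise(
      mean_corner_length_um = .data$mean_corner_length_um[1],
      baseline_flow_1e12_m3s = .data$acu_flow_1e12_m3s[.data$timepoint_min == 0],
      final_pct_jv_per_surface = .data$pct_jv_per_surface[which.max(.data$timepoint_min)],
      .groups = "drop"
    )
}
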