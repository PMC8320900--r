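# The ACU network container: a typed planar vessel graph.
#
# Node kinds: corner_junction, septal_junction, inlet, outlet.
# Edge kinds: corner (10-50 μm, along alveolar edges), septal (5-8 μm wall
# capillaries), distribution (upstream/downstream stubs). Lengths and diameters
# in μm.

#' Construct an ACU vessel network
#'
#' Low-level constructor for the alveolar capillary unit network: a planar
#' graph of typed vessel segments. Most users obtain networks from
#' [generate_acu_skeleton()] and [build_septal_mesh()] rather than calling this
#' directly.
#'
#' @param nodes Tibble with columns `id` (integer, unique), `x_um`, `y_um`,
#'   `kind` (one of `"corner_junction"`, `"septal_junction"`, `"inlet"`,
#'   `"outlet"`).
#' @param edges Tibble with columns `id`, `from`, `to` (node ids), `kind`
#'   (`"corner"`, `"septal"`, `"distribution"`), `diameter_um`, `length_um`,
#'   and optionally `corner_id` (parent corner vessel for subdivided corner
#'   segments).
#' @param inlets,outlets Integer vectors of node ids acting as arteriolar
#'   access / venular exit points (disjoint).
#' @param polygon Corner-cycle polygon vertex matrix (μm), or `NULL` for
#'   free-form test networks.
#' @param barrier_um Alveolar barrier thickness (μm) used by the 2D-to-volume
#'   bridge; defaults to the mean septal diameter, 6.5 μm.
#' @param validate Run structural validation.
#' @return An object of class `acu_network`.
#' @export
acu_network <- function(nodes, edges, inlets = integer(), outlets = integer(),
                        polygon = NULL, barrier_um = 6.5, validate = TRUE) {
  nodes <- as_tibble(nodes)
  edges <- as_tibble(edges)
  if (!"corner_id" %in% names(edges)) edges$corner_id <- NA_integer_
  net <- structure(
    list(
      nodes = nodes[, c("id", "x_um", "y_um", "kind")],
      edges = edges[, c("id", "from", "to", "kind", "diameter_um", "length_um", "corner_id")],
      inlets = as.integer(inlets),
      outlets = as.integer(outlets),
      polygon = if (!is.null(polygon)) as_vertex_matrix(polygon) else NULL,
      barrier_um = barrier_um
    ),
    class = "acu_network"
  )
  if (validate) validate_acu_network(net)
  net
}

validate_acu_network <- function(net) {
  n <- net$nodes; e <- net$edges
  if (anyDuplicated(n$id)) abort("node ids must be unique")
  if (!all(is.finite(n$x_um)) || !all(is.finite(n$y_um))) abort("node positions must be finite")
  if (!all(n$kind %in% c("corner_junction", "septal_junction", "inlet", "outlet")))
    abort("unknown node kind")
  if (!all(e$kind %in% c("corner", "septal", "distribution"))) abort("unknown edge kind")
  if (!all(c(e$from, e$to) %in% n$id)) abort("edge endpoint not among nodes")
  if (any(e$length_um <= 0)) abort("edge lengths must be positive")
  if (any(e$diameter_um < 0)) abort("edge diameters must be non-negative")
  if (length(intersect(net$inlets, net$outlets)) > 0) abort("inlet and outlet node sets must be disjoint")
  if (!all(c(net$inlets, net$outlets) %in% n$id)) abort("inlet/outlet ids must be nodes")
  if (nrow(e) > 0) {
    g <- igraph::graph_from_data_frame(
      data.frame(from = as.character(e$from), to = as.character(e$to)),
      directed = FALSE, vertices = data.frame(name = as.character(n$id))
    )
    if (igraph::components(g)$no > 1) abort("network graph must be connected")
  }
  if (!is.null(net$polygon)) {
    ce <- e[e$kind == "corner", ]
    if (nrow(ce) < 3) abort("corner cycle requires at least 3 corner edges")
    ids <- c(ce$from, ce$to)
    deg <- table(ids)
    if (any(deg != 2)) abort("corner edges must form a single closed cycle (each corner node of corner-degree 2)")
    gc <- igraph::graph_from_data_frame(
      data.frame(from = as.character(ce$from), to = as.character(ce$to)), directed = FALSE
    )
    if (igraph::components(gc)$no != 1) abort("corner edges must form a single closed cycle")
    # septal edges must lie inside the polygon
    se <- e[e$kind == "septal", ]
    if (nrow(se) > 0) {
      pos <- as.matrix(n[, c("x_um", "y_um")])
      idx <- match(se$from, n$id); idy <- match(se$to, n$id)
      mids <- (pos[idx, , drop = FALSE] + pos[idy, , drop = FALSE]) / 2
      if (!all(points_in_polygon(mids, net$polygon, tol = 1e-3)))
        abort("septal edge midpoints must lie inside the ACU polygon")
    }
  }
  invisible(net)
}

#' @export
print.acu_network <- function(x, ...) {
  kinds <- table(x$edges$kind)
  cat("<acu_network> ", nrow(x$nodes), " nodes, ", nrow(x$edges), " edges (",
      paste(names(kinds), as.integer(kinds), collapse = ", "), ")\n", sep = "")
  cat("  inlets: ", paste(x$inlets, collapse = ", "),
      " | outlets: ", paste(x$outlets, collapse = ", "), "\n", sep = "")
  if (!is.null(x$polygon)) {
    mcl <- mean_corner_length(x)
    cat(sprintf("  ACU polygon area %.0f um^2, mean corner length %.1f +/- %.1f um\n",
                polygon_area(x$polygon), mcl$mean_um, mcl$sd_um))
  }
  invisible(x)
}

node_positions <- function(net) {
  m <- as.matrix(net$nodes[, c("x_um", "y_um")])
  rownames(m) <- net$nodes$id
  m
}

#' Mean and standard deviation of corner vessel lengths
#'
#' Summarises the corner vessels of an ACU network (the Table-2 style
#' "mean corner length"). Corner segments subdivided by septal junctions are
#' re-aggregated to their parent corner vessel via `corner_id`.
#'
#' @param net An `acu_network`.
#' @return One-row tibble with `n_corner`, `mean_um`, `sd_um`.
#' @export
mean_corner_length <- function(net) {
  ce <- net$edges[net$edges$kind == "corner", ]
  if (nrow(ce) == 0) abort("network has no corner edges")
  grp <- if_else(is.na(ce$corner_id), ce$id, ce$corner_id)
  lens <- tapply(ce$length_um, grp, sum)
  tibble(n_corner = length(lens), mean_um = mean(lens),
         sd_um = if (length(lens) > 1) sd(lens) else 0)
}

#' Capillary (septal) blood volume of a network
#'
#' Sum of cylinder volumes \eqn{(\pi/4) d^2 L} over septal edges. Corner and
#' distribution vessels are excluded: the morphological volume-ratio constraint
#' concerns the septal capillary mesh only.
#'
#' @param net An `acu_network`.
#' @return Volume in μm³.
#' @export
capillary_volume <- function(net) {
  se <- net$edges[net$edges$kind == "septal", ]
  if (nrow(se) == 0) return(0)
  sum(pi / 4 * se$diameter_um^2 * se$length_um)
}

#' Interstitial alveolar volume of a network
#'
#' 2D-to-volume bridge: the ACU polygon area times the barrier thickness,
#' minus the capillary volume occupying that slab.
#'
#' @param net An `acu_network` with a polygon and `barrier_um > 0`.
#' @return Volume in μm³.
#' @export
interstitial_volume <- function(net) {
  if (is.null(net$polygon)) abort("network has no ACU polygon")
  if (is.null(net$barrier_um) || net$barrier_um <= 0) abort("barrier thickness must be positive")
  v <- polygon_area(net$polygon) * net$barrier_um - capillary_volume(net)
  if (v <= 0) abort("over-dense mesh: capillary volume exceeds the barrier slab volume")
  v
}

#' Achieved capillary-to-interstitial volume ratio
#'
#' @param net An `acu_network`.
#' @return Dimensionless ratio.
#' @export
volume_ratio <- function(net) capillary_volume(net) / interstitial_volume(net)

#' Serialize an ACU network to JSON
#'
#' Canonical key order; lengths are persisted (not recomputed on read) so that
#' write/read/write round-trips are byte-identical.
#'
#' @param net An `acu_network`.
#' @param path Output file path; `NULL` returns the JSON string.
#' @return The JSON string, invisibly when written to a file.
#' @export
write_acu_network <- function(net, path = NULL) {
  obj <- list(
    nodes = net$nodes,
    edges = net$edges,
    inlets = net$inlets,
    outlets = net$outlets,
    barrier_thickness_um = net$barrier_um,
    polygon_um = if (!is.null(net$polygon)) unname(net$polygon) else NULL
  )
  js <- jsonlite::toJSON(obj, dataframe = "columns", digits = NA, auto_unbox = TRUE,
                         null = "null", pretty = FALSE)
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(as.character(js))
}

#' Read an ACU network from JSON
#'
#' @param path File path or JSON string produced by [write_acu_network()].
#' @return An `acu_network`.
#' @export
read_acu_network <- function(path) {
  obj <- jsonlite::fromJSON(path)
  poly <- obj$polygon_um
  if (!is.null(poly)) poly <- matrix(unlist(poly), ncol = 2,
                                     byrow = !is.matrix(poly) && is.list(poly))
  if (is.list(obj$polygon_um) && !is.matrix(obj$polygon_um)) {
    poly <- do.call(rbind, obj$polygon_um)
  } else if (!is.null(obj$polygon_um)) {
    poly <- as.matrix(obj$polygon_um)
  }
  acu_network(
    nodes = as_tibble(obj$nodes),
    edges = as_tibble(obj$edges),
    inlets = obj$inlets %||% integer(),
    outlets = obj$outlets %||% integer(),
    polygon = poly,
    barrier_um = obj$barrier_thickness_um %||% 6.5
  )
}
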