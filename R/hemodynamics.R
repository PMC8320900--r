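# Steady Poiseuille perfusion of the ACU network: a weighted graph-Laplacian
# Dirichlet problem (arteriolar pressure at inlets, venular pressure at
# outlets) alternated with a binary transmural-pressure patency rule for the
# septal capillaries until the patent set is stable.

CMH2O_PA <- 98.0665  # 1 cmH2O in Pa

#' Pressure boundary conditions for one timepoint
#'
#' @param P_art Arteriolar inlet pressure (cmH₂O).
#' @param P_ven Venular outlet pressure (cmH₂O).
#' @param P_i Peri-microvascular interstitial pressure (cmH₂O); rises from
#'   about -10 toward +3 cmH₂O as interstitial edema develops.
#' @param label Timepoint label.
#' @return A `pressure_boundary` list.
#' @export
pressure_boundary <- function(P_art = 16, P_ven = 6, P_i = -10, label = "baseline") {
  if (P_art <= P_ven) abort("P_art must exceed P_ven (forward flow)")
  structure(list(P_art = P_art, P_ven = P_ven, P_i = P_i, label = label),
            class = "pressure_boundary")
}

#' Edema time-course pressure table
#'
#' The default boundary pressures for the three reference timepoints of the
#' hypoxia protocol: arteriolar pressure constant at 16 cmH₂O, mild venular
#' venoconstriction (6 to 8 cmH₂O), and interstitial pressure rising from -10
#' to +3 cmH₂O with developing interstitial edema.
#'
#' @return Tibble with `timepoint_min`, `label`, `P_art`, `P_ven`, `P_i`
#'   (cmH₂O).
#' @export
pressure_table <- function() {
  tibble(
    timepoint_min = c(0, 30, 120),
    label = c("baseline", "30 min", "120 min"),
    P_art = c(16, 16, 16),
    P_ven = c(6, 8, 8),
    P_i = c(-10, -6, 3)
  )
}

#' Physiological and numerical parameters of the perfusion model
#'
#' @param viscosity Blood viscosity μ in Pa·s (constant, no diameter-dependent
#'   rheology).
#' @param p_close Transmural-pressure closure threshold (cmH₂O): a septal edge
#'   is patent iff its mean luminal pressure minus `P_i` exceeds this.
#' @param max_iter Cap on patency fixed-point iterations.
#' @return A `physio_params` list.
#' @export
physio_params <- function(viscosity = 2e-3, p_close = 0, max_iter = 100L) {
  if (viscosity <= 0) abort("viscosity must be positive")
  structure(list(viscosity = viscosity, p_close = p_close, max_iter = max_iter),
            class = "physio_params")
}

#' Hagen-Poiseuille conductance of a cylindrical vessel segment
#'
#' \eqn{g = \pi d^4 / (128 \mu L)} with diameter and length converted from μm
#' to metres. Non-patent or zero-diameter segments have zero conductance.
#'
#' @param diameter_um,length_um Segment diameter and length (μm), vectorised.
#' @param viscosity Blood viscosity (Pa·s).
#' @param patent Logical patency flags (recycled).
#' @return Conductance in m³/(s·Pa).
#' @export
edge_conductance <- function(diameter_um, length_um, viscosity = 2e-3, patent = TRUE) {
  d <- diameter_um * 1e-6; L <- length_um * 1e-6
  g <- pi * d^4 / (128 * viscosity * L)
  g[!rep_len(patent, length(g)) | d <= 0] <- 0
  g
}

#' Solve node pressures under Dirichlet inlet/outlet conditions
#'
#' Solves flow conservation on the patent network: inlets held at `P_art`,
#' outlets at `P_ven`, interior pressures from the weighted graph Laplacian.
#' Patent components with no path to any boundary node are stagnant and sit at
#' the interstitial pressure `P_i`.
#'
#' @param net An `acu_network`.
#' @param bc A [pressure_boundary()].
#' @param patent Logical vector over edges (default all patent).
#' @param params A [physio_params()].
#' @return Numeric vector of node pressures (cmH₂O), named by node id.
#' @export
solve_pressures <- function(net, bc, patent = NULL, params = physio_params()) {
  e <- net$edges
  patent <- patent %||% rep(TRUE, nrow(e))
  g <- edge_conductance(e$diameter_um, e$length_um, params$viscosity, patent)
  ids <- net$nodes$id
  n <- length(ids)
  iu <- match(e$from, ids); iv <- match(e$to, ids)
  p <- rep(bc$P_i, n)
  bnd <- match(c(net$inlets, net$outlets), ids)
  pb <- c(rep(bc$P_art, length(net$inlets)), rep(bc$P_ven, length(net$outlets)))
  if (length(bnd) == 0) abort("network has no inlet or outlet nodes")
  live <- g > 0
  if (!any(live)) { p[bnd] <- pb; names(p) <- ids; return(p) }
  # connected components of the conducting subgraph
  gg <- igraph::graph_from_data_frame(
    data.frame(from = as.character(e$from[live]), to = as.character(e$to[live])),
    directed = FALSE, vertices = data.frame(name = as.character(ids))
  )
  comp <- igraph::components(gg)$membership[as.character(ids)]
  fed <- comp %in% unique(comp[bnd])
  free <- which(fed & !(seq_len(n) %in% bnd))
  p[bnd] <- pb
  if (length(free) > 0) {
    keep <- live & fed[iu] & fed[iv]
    L <- Matrix::sparseMatrix(
      i = c(iu[keep], iv[keep], iu[keep], iv[keep]),
      j = c(iv[keep], iu[keep], iu[keep], iv[keep]),
      x = c(-g[keep], -g[keep], g[keep], g[keep]),
      dims = c(n, n)
    )
    rhs <- -L[free, bnd, drop = FALSE] %*% pb
    sol <- Matrix::solve(L[free, free, drop = FALSE], rhs)
    p[free] <- as.numeric(sol)
  }
  names(p) <- ids
  p
}

#' Update septal patency from a pressure solution
#'
#' A septal edge is patent iff the mean of its endpoint pressures minus the
#' interstitial pressure exceeds the closure threshold (a binary transmural
#' rule). Corner vessels are kept patent by parenchymal elastic tension, and
#' distribution vessels never close here (their measured diameters carry any
#' closure instead).
#'
#' @param net An `acu_network`.
#' @param pressures Node pressures from [solve_pressures()].
#' @param bc A [pressure_boundary()].
#' @param params A [physio_params()].
#' @return Logical patency vector over edges.
#' @export
update_patency <- function(net, pressures, bc, params = physio_params()) {
  e <- net$edges
  pm <- (pressures[as.character(e$from)] + pressures[as.character(e$to)]) / 2
  patent <- rep(TRUE, nrow(e))
  sep <- e$kind == "septal"
  patent[sep] <- (pm[sep] - bc$P_i) > params$p_close
  unname(patent)
}

#' Steady perfusion of an ACU network with de-recruitment
#'
#' Fixed-point iteration alternating [solve_pressures()] and
#' [update_patency()], starting from the all-patent state. On a two-cycle
#' oscillation the smaller patent set is taken (the de-recruited reading).
#' Flows are reported per edge together with the ACU throughflow and the
#' septal-to-corner flow split measured on the mid-pressure cut (nodes above
#' vs below \eqn{P^* = (P_{art}+P_{ven})/2}; every cut edge carries flow from
#' the high side to the low side, and the kind-wise cut flows sum exactly to
#' the ACU flow).
#'
#' @param net An `acu_network`.
#' @param bc A [pressure_boundary()].
#' @param params A [physio_params()].
#' @return An `acu_perfusion`: node pressures, per-edge tibble (`id`, `kind`,
#'   `patent`, `flow_m3s`, `mean_pressure_cmH2O`), `acu_flow_m3s`,
#'   `corner_flow_m3s`, `septal_flow_m3s`, `septal_to_corner_ratio`,
#'   `fully_derecruited`, iteration count, and the boundary used.
#' @export
perfuse <- function(net, bc, params = physio_params()) {
  stopifnot(inherits(net, "acu_network"), inherits(bc, "pressure_boundary"))
  e <- net$edges
  patent <- rep(TRUE, nrow(e))
  seen <- list(patent)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    p <- solve_pressures(net, bc, patent, params)
    newpat <- update_patency(net, p, bc, params)
    if (identical(newpat, patent)) break
    hit <- Position(function(s) identical(s, newpat), seen)
    if (!is.null(hit) && !is.na(hit)) {
      # oscillation (limit cycle): take the de-recruited reading, i.e. an edge
      # is patent only if it stayed patent in every state of the cycle
      cyc <- seen[seq(hit, length(seen))]
      patent <- Reduce(`&`, cyc) & newpat
      p <- solve_pressures(net, bc, patent, params)
      break
    }
    if (iter >= params$max_iter) {
      abort(sprintf("patency fixed point did not converge in %d iterations (last sets: %d vs %d patent)",
                    params$max_iter, sum(patent), sum(newpat)))
    }
    seen <- c(seen, list(newpat))
    patent <- newpat
  }
  g <- edge_conductance(e$diameter_um, e$length_um, params$viscosity, patent)
  dp <- p[as.character(e$from)] - p[as.character(e$to)]
  q <- unname(g * dp * CMH2O_PA)
  pm <- unname((p[as.character(e$from)] + p[as.character(e$to)]) / 2)
  # ACU throughflow: total flow leaving the inlet nodes
  sgn_from <- as.integer(e$from %in% net$inlets) - as.integer(e$to %in% net$inlets)
  acu_flow <- sum(q * sgn_from)
  # mid-pressure cut accounting
  pstar <- (bc$P_art + bc$P_ven) / 2
  hi <- p >= pstar
  hu <- unname(hi[as.character(e$from)]); hv <- unname(hi[as.character(e$to)])
  crossing <- hu != hv
  cutflow <- ifelse(hu, q, -q)        # flow from the high side to the low side
  cut_by_kind <- function(kind) sum(cutflow[crossing & e$kind == kind])
  corner_flow <- cut_by_kind("corner")
  septal_flow <- cut_by_kind("septal")
  ratio <- if (corner_flow > 0) septal_flow / corner_flow else NA_real_
  # fully de-recruited: no conducting path joins an inlet to an outlet
  fully <- abs(acu_flow) <= .Machine$double.eps * 100
  structure(list(
    node_pressures = tibble(id = net$nodes$id, pressure_cmH2O = unname(p)),
    edges = tibble(id = e$id, kind = e$kind, patent = patent,
                   flow_m3s = q, mean_pressure_cmH2O = pm,
                   diameter_um = e$diameter_um, length_um = e$length_um,
                   from = e$from, to = e$to),
    acu_flow_m3s = acu_flow,
    corner_flow_m3s = corner_flow,
    septal_flow_m3s = septal_flow,
    distribution_cut_flow_m3s = cut_by_kind("distribution"),
    septal_to_corner_ratio = ratio,
    fully_derecruited = fully,
    iterations = iter,
    bc = bc,
    params = params,
    network = net
  ), class = "acu_perfusion")
}

#' @export
print.acu_perfusion <- function(x, ...) {
  np <- sum(x$edges$patent[x$edges$kind == "septal"])
  ns <- sum(x$edges$kind == "septal")
  cat(sprintf("<acu_perfusion> %s: ACU flow %.3g m^3/s, septal/corner ratio %.3g, %d/%d septal edges patent%s\n",
              x$bc$label, x$acu_flow_m3s, x$septal_to_corner_ratio, np, ns,
              if (x$fully_derecruited) " [fully de-recruited]" else ""))
  invisible(x)
}
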