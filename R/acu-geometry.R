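# Building the septal capillary mesh inside a corner-vessel polygon by
# constrained Voronoi tessellation, calibrating the interior point count to a
# target capillary-to-interstitial volume ratio, and attaching the arteriolar
# inlet / venular outlet stubs.

#' Build the septal mesh of an ACU by constrained Voronoi tessellation
#'
#' Samples `n_points` uniform interior generator points, computes their Voronoi
#' diagram clipped to the corner polygon, and turns interior ridges into septal
#' edges. Ridge-boundary intersections subdivide the corner vessels and join
#' the two meshes; subdivided corner segments inherit the diameter of their
#' parent corner vessel. Septal diameters are sampled i.i.d. uniform on
#' `septal_diameter_range`.
#'
#' @param skeleton An `acu_network` corner skeleton (from
#'   [generate_acu_skeleton()] or image annotation).
#' @param n_points Number of interior Voronoi generator points (>= 1).
#' @param seed Integer seed (generator points and septal diameters).
#' @param septal_diameter_range Septal diameter band in μm (default 5-8, the
#'   septal capillary class).
#' @return An `acu_network` with corner + septal edges.
#' @export
build_septal_mesh <- function(skeleton, n_points, seed = 1L,
                              septal_diameter_range = c(5, 8)) {
  stopifnot(inherits(skeleton, "acu_network"), n_points >= 1)
  poly <- skeleton$polygon
  if (is.null(poly)) abort("skeleton must carry the corner polygon")
  np <- nrow(poly)
  pts <- local_rng(seed, sample_points_in_polygon(n_points, poly))
  mesh <- voronoi_mesh(pts, poly)
  nodes <- mesh$nodes
  segs <- mesh$segments
  scale <- max(1, max(abs(poly)))
  nd_bdist <- dist_to_polyline(nodes, rbind(poly, poly[1, ]))
  on_bnd <- nd_bdist <= 1e-6 * scale
  # order boundary nodes along the corner cycle: (polygon edge, position along)
  k_of <- rep(NA_integer_, nrow(nodes)); t_of <- rep(NA_real_, nrow(nodes))
  bidx <- which(on_bnd)
  if (length(bidx)) {
    bpts <- nodes[bidx, , drop = FALSE]
    best <- rep(Inf, length(bidx)); bk <- integer(length(bidx)); bt <- numeric(length(bidx))
    for (k in seq_len(np)) {
      a <- poly[k, ]; b <- poly[if (k == np) 1L else k + 1L, ]
      d <- dist_point_segment(bpts, a, b)
      ab <- b - a
      t <- ((bpts[, 1] - a[1]) * ab[1] + (bpts[, 2] - a[2]) * ab[2]) / sum(ab^2)
      upd <- d < best & t > -1e-9 & t < 1 + 1e-9
      best[upd] <- d[upd]; bk[upd] <- k; bt[upd] <- pmin(1, pmax(0, t[upd]))
    }
    # a polygon vertex sits at t ~ 1 of edge k-1 and t ~ 0 of edge k; canonicalise
    vert_like <- bt > 1 - 1e-9
    bk[vert_like] <- bk[vert_like] %% np + 1L
    bt[vert_like] <- 0
    k_of[bidx] <- bk; t_of[bidx] <- bt
  }
  ord_b <- bidx[order(k_of[bidx], t_of[bidx])]
  ord_i <- setdiff(order(nodes[, 1], nodes[, 2]), which(on_bnd))
  old2new <- integer(nrow(nodes))
  old2new[c(ord_b, ord_i)] <- seq_len(nrow(nodes))
  n_bnd <- length(ord_b)
  new_nodes <- tibble(
    id = seq_len(nrow(nodes)),
    x_um = nodes[c(ord_b, ord_i), 1],
    y_um = nodes[c(ord_b, ord_i), 2],
    kind = c(rep("corner_junction", n_bnd), rep("septal_junction", length(ord_i)))
  )
  # corner edges: consecutive boundary nodes along the cycle
  bseq <- old2new[ord_b]                      # 1..n_bnd in cycle order
  k_sorted <- k_of[ord_b]
  ce_from <- bseq
  ce_to <- c(bseq[-1], bseq[1])
  parent <- k_sorted                          # segment i spans edge k_sorted[i] of the polygon
  sk_edges <- skeleton$edges[skeleton$edges$kind == "corner", ]
  sk_edges <- sk_edges[order(sk_edges$id), ]
  ce_len <- sqrt((new_nodes$x_um[ce_to] - new_nodes$x_um[ce_from])^2 +
                 (new_nodes$y_um[ce_to] - new_nodes$y_um[ce_from])^2)
  corner <- tibble(
    from = ce_from, to = ce_to, kind = "corner",
    diameter_um = sk_edges$diameter_um[parent],
    length_um = ce_len,
    corner_id = sk_edges$corner_id[parent]
  )
  sep <- segs[!segs$on_boundary & segs$inside & segs$length > 1e-6 * scale, , drop = FALSE]
  septal <- tibble(
    from = old2new[sep$u], to = old2new[sep$v], kind = "septal",
    diameter_um = NA_real_, length_um = sep$length, corner_id = NA_integer_
  )
  if (nrow(septal) > 0) {
    sw <- pmin(septal$from, septal$to); lg <- pmax(septal$from, septal$to)
    o <- order(sw, lg)
    septal <- septal[o, ]
    septal$from <- sw[o]; septal$to <- lg[o]
    septal$diameter_um <- local_rng(
      child_seed(seed, 3),
      runif(nrow(septal), septal_diameter_range[1], septal_diameter_range[2])
    )
  }
  edges <- bind_rows(corner, septal)
  edges$id <- seq_len(nrow(edges))
  edges <- edges[, c("id", "from", "to", "kind", "diameter_um", "length_um", "corner_id")]
  # concave polygons can orphan interior vertices whose every ridge was a
  # clipping artifact; prune unreferenced nodes and compact the ids
  used <- sort(unique(c(edges$from, edges$to)))
  if (length(used) < nrow(new_nodes)) {
    remap <- integer(nrow(new_nodes))
    remap[used] <- seq_along(used)
    new_nodes <- new_nodes[used, ]
    new_nodes$id <- seq_along(used)
    edges$from <- remap[edges$from]
    edges$to <- remap[edges$to]
  }
  # carry inlet/outlet designations over by junction coordinates
  skn <- skeleton$nodes
  map_junction <- function(ids) {
    vapply(ids, function(i) {
      p <- c(skn$x_um[skn$id == i], skn$y_um[skn$id == i])
      which.min((new_nodes$x_um - p[1])^2 + (new_nodes$y_um - p[2])^2)
    }, integer(1))
  }
  acu_network(new_nodes, edges,
              inlets = map_junction(skeleton$inlets),
              outlets = map_junction(skeleton$outlets),
              polygon = poly, barrier_um = skeleton$barrier_um)
}

#' Calibrate the interior point count to a target volume ratio
#'
#' The capillary-to-interstitial volume ratio of the generated septal mesh
#' grows with the number of interior Voronoi points N (total ridge length
#' scales like the square root of N). This search returns the smallest N whose
#' mean achieved ratio over `replicates` seeded meshes falls within `tol` of
#' `target_ratio` (1.54, the morphological constraint for the fully extended
#' rabbit capillary network).
#'
#' @param skeleton An `acu_network` corner skeleton with polygon and barrier
#'   thickness.
#' @param target_ratio Target capillary-to-interstitial volume ratio.
#' @param tol Absolute tolerance on the mean achieved ratio.
#' @param replicates Seed replicates per N (the mesh is stochastic in N).
#' @param seed Base seed; replicate seeds are derived from it and shared
#'   across N values (common random numbers).
#' @param n_max Upper bound on N before declaring the target unreachable.
#' @param septal_diameter_range Septal diameter band (μm).
#' @return An `acu_calibration`: list with `n_points`, `achieved_ratio`,
#'   `target_ratio`, `tol`, `replicates`.
#' @export
calibrate_n_points <- function(skeleton, target_ratio = 1.54, tol = 0.05,
                               replicates = 5, seed = 1L, n_max = 5000L,
                               septal_diameter_range = c(5, 8)) {
  stopifnot(inherits(skeleton, "acu_network"))
  if (target_ratio <= 0) abort("infeasible target ratio: must be positive")
  cache <- new.env(parent = emptyenv())
  g <- function(N) {
    key <- as.character(N)
    if (!is.null(cache[[key]])) return(cache[[key]])
    r <- mean(vapply(seq_len(replicates), function(rr) {
      volume_ratio(build_septal_mesh(skeleton, N, seed = child_seed(seed, rr),
                                     septal_diameter_range = septal_diameter_range))
    }, numeric(1)))
    cache[[key]] <- r
    r
  }
  # exponential bracket, then binary search for the smallest N reaching the band
  hi <- 4L
  while (g(hi) < target_ratio && hi < n_max) hi <- min(2L * hi, as.integer(n_max))
  if (g(hi) < target_ratio - tol) {
    abort(sprintf(
      "target ratio %.3f unreachable below n_max = %d: achievable range is [0, %.3f]",
      target_ratio, n_max, g(hi)))
  }
  lo <- 1L   # a single interior point yields no septal edges: ratio 0
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (g(mid) >= target_ratio - tol) hi <- mid else lo <- mid
  }
  achieved <- g(hi)
  if (abs(achieved - target_ratio) > tol) {
    abort(sprintf(
      "calibration jumped over the tolerance band: N = %d achieves %.3f (target %.3f +/- %.3f)",
      hi, achieved, target_ratio, tol))
  }
  structure(list(n_points = hi, achieved_ratio = achieved,
                 target_ratio = target_ratio, tol = tol, replicates = replicates,
                 seed = seed),
            class = "acu_calibration")
}

#' @export
print.acu_calibration <- function(x, ...) {
  cat(sprintf("<acu_calibration> N = %d interior points, achieved ratio %.3f (target %.2f +/- %.2f over %d replicates)\n",
              x$n_points, x$achieved_ratio, x$target_ratio, x$tol, x$replicates))
  invisible(x)
}

#' Attach arteriolar inlets and venular outlets to an ACU network
#'
#' Snaps each requested inlet/outlet position to the nearest corner-cycle node
#' and adds an external access node joined by a distribution-vessel stub.
#' Optionally validates the full-perfusion condition: under baseline pressures
#' every septal edge must carry nonzero flow (a warning lists unperfused edges
#' otherwise).
#'
#' @param net An `acu_network` (skeleton or meshed).
#' @param inlet_positions,outlet_positions Matrices (rows = points, μm) of
#'   access positions near the corner cycle.
#' @param distribution_diameter Diameter of the distribution stubs (μm),
#'   recycled; default 50 μm (terminal subpleural arterioles).
#' @param stub_length_min Minimum stub length (μm) when a position coincides
#'   with its snapped node.
#' @param validate Check baseline full perfusion by solving the network under
#'   `bc`.
#' @param bc Baseline [pressure_boundary()] used for the validation solve.
#' @param params [physio_params()] for the validation solve.
#' @return The network with external inlet/outlet nodes and distribution
#'   edges; `inlets`/`outlets` now name the external nodes.
#' @export
attach_boundary <- function(net, inlet_positions, outlet_positions,
                            distribution_diameter = 50, stub_length_min = 20,
                            validate = TRUE, bc = pressure_boundary(),
                            params = physio_params()) {
  stopifnot(inherits(net, "acu_network"))
  ip <- matrix(as.numeric(inlet_positions), ncol = 2)
  op <- matrix(as.numeric(outlet_positions), ncol = 2)
  for (i in seq_len(nrow(ip))) {
    for (j in seq_len(nrow(op))) {
      if (max(abs(ip[i, ] - op[j, ])) < 1e-9)
        abort("an inlet position equals an outlet position")
    }
  }
  ce <- net$edges[net$edges$kind == "corner", ]
  cyc_ids <- unique(c(ce$from, ce$to))
  if (length(cyc_ids) == 0) abort("network has no corner cycle to attach to")
  pos <- node_positions(net)
  cyc_pos <- pos[match(cyc_ids, net$nodes$id), , drop = FALSE]
  snap_to_cycle <- function(p) cyc_ids[which.min((cyc_pos[, 1] - p[1])^2 + (cyc_pos[, 2] - p[2])^2)]
  in_anchor <- apply(ip, 1, snap_to_cycle)
  out_anchor <- apply(op, 1, snap_to_cycle)
  if (length(intersect(in_anchor, out_anchor)) > 0)
    abort("an inlet and an outlet snap to the same corner node")
  nid0 <- max(net$nodes$id)
  eid0 <- max(net$edges$id)
  n_new <- nrow(ip) + nrow(op)
  ext <- tibble(
    id = nid0 + seq_len(n_new),
    x_um = c(ip[, 1], op[, 1]),
    y_um = c(ip[, 2], op[, 2]),
    kind = c(rep("inlet", nrow(ip)), rep("outlet", nrow(op)))
  )
  anchors <- c(in_anchor, out_anchor)
  apos <- pos[match(anchors, net$nodes$id), , drop = FALSE]
  stub_len <- pmax(sqrt((ext$x_um - apos[, 1])^2 + (ext$y_um - apos[, 2])^2), stub_length_min)
  dd <- rep_len(distribution_diameter, n_new)
  stubs <- tibble(
    id = eid0 + seq_len(n_new), from = ext$id, to = anchors,
    kind = "distribution", diameter_um = dd, length_um = stub_len,
    corner_id = NA_integer_
  )
  out <- acu_network(bind_rows(net$nodes, ext), bind_rows(net$edges, stubs),
                     inlets = ext$id[ext$kind == "inlet"],
                     outlets = ext$id[ext$kind == "outlet"],
                     polygon = net$polygon, barrier_um = net$barrier_um)
  if (validate && any(out$edges$kind == "septal")) {
    sol <- perfuse(out, bc, params)
    se <- sol$edges[sol$edges$kind == "septal", ]
    dead <- se$id[abs(se$flow_m3s) <= 1e-12 * max(abs(sol$edges$flow_m3s))]
    if (length(dead) > 0) {
      warn(paste0("baseline full-perfusion check failed: ", length(dead),
                  " septal edge(s) carry no flow (ids ",
                  paste(utils::head(dead, 10), collapse = ", "),
                  if (length(dead) > 10) ", ..." else "", ")"),
           class = "acuflow_unperfused")
    }
  }
  out
}
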