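# Polygon-constrained Voronoi tessellation by incremental half-plane clipping.
#
# The cell of generator i is the ACU polygon successively clipped by the
# perpendicular-bisector half-planes against the other generators, visited in
# order of increasing distance. Once the bisector distance d_j/2 exceeds the
# farthest current cell vertex from the generator, no later generator can cut
# the cell and the loop stops, giving near-linear cost per cell for uniform
# points.

#' Voronoi cells of points clipped to a polygon
#'
#' Computes the constrained (polygon-clipped) Voronoi tessellation of a set of
#' generator points. Cells are convex polygons intersected with `polygon`.
#'
#' @param points n x 2 matrix of generator coordinates (μm), inside `polygon`.
#' @param polygon Simple polygon vertex matrix (μm).
#' @param max_retries Number of re-perturbation attempts for degenerate
#'   (duplicate-generator) configurations.
#' @return List of vertex matrices, one convex cell per generator, in input
#'   order.
#' @export
clipped_voronoi <- function(points, polygon, max_retries = 3L) {
  polygon <- ensure_ccw(as_vertex_matrix(polygon))
  points <- matrix(as.numeric(points), ncol = 2)
  n <- nrow(points)
  if (n < 1) abort("need at least one generator point")
  scale <- max(apply(polygon, 2, function(v) diff(range(v))))
  for (try in 0:max_retries) {
    if (n == 1 || min_pairwise_gap(points) > 1e-9 * scale) break
    if (try == max_retries) abort("degenerate Voronoi generators: duplicate points persist after retries")
    points <- points + matrix(rnorm(2 * n, sd = 1e-6 * scale), n, 2)
  }
  cells <- vector("list", n)
  for (i in seq_len(n)) {
    cell <- polygon
    if (n > 1) {
      p <- points[i, ]
      d2 <- (points[, 1] - p[1])^2 + (points[, 2] - p[2])^2
      ord <- order(d2)
      ord <- ord[ord != i]
      for (j in ord) {
        rmax2 <- max((cell[, 1] - p[1])^2 + (cell[, 2] - p[2])^2)
        if (d2[j] > 4 * rmax2) break
        q <- points[j, ]
        nvec <- q - p
        cval <- sum(nvec * (p + q) / 2)
        cell <- clip_halfplane(cell, nvec, cval)
        if (nrow(cell) < 3) break
      }
    }
    if (nrow(cell) < 3) abort("degenerate Voronoi cell (generator outside polygon?)")
    cells[[i]] <- cell
  }
  cells
}

min_pairwise_gap <- function(points) {
  if (nrow(points) < 2) return(Inf)
  min(stats::dist(points))
}

# Decompose the clipped tessellation into a planar mesh:
#   * nodes: snapped unique vertices,
#   * interior ridges (segments shared by two cells) -> septal candidates,
#   * boundary segments (on the polygon outline) -> corner subdivisions,
# with each boundary segment tagged by the polygon edge it lies on.
voronoi_mesh <- function(points, polygon, snap_tol = 1e-6) {
  polygon <- ensure_ccw(as_vertex_matrix(polygon))
  cells <- clipped_voronoi(points, polygon)
  segs_a <- list(); segs_b <- list()
  for (cell in cells) {
    m <- nrow(cell)
    nxt <- c(2:m, 1)
    segs_a[[length(segs_a) + 1L]] <- cell
    segs_b[[length(segs_b) + 1L]] <- cell[nxt, , drop = FALSE]
  }
  A <- do.call(rbind, segs_a)
  B <- do.call(rbind, segs_b)
  # include the polygon vertices so that corner junctions always exist as nodes
  allpts <- rbind(A, B, polygon)
  sn <- snap_points(allpts, tol = snap_tol)
  nseg <- nrow(A)
  ia <- sn$id[seq_len(nseg)]
  ib <- sn$id[nseg + seq_len(nseg)]
  nodes <- sn$coords
  keep <- ia != ib
  ia <- ia[keep]; ib <- ib[keep]
  lo <- pmin(ia, ib); hi <- pmax(ia, ib)
  key <- paste(lo, hi)
  first <- !duplicated(key)
  cnt <- table(key)
  seg_lo <- lo[first]; seg_hi <- hi[first]
  seg_cnt <- as.integer(cnt[paste(seg_lo, seg_hi)])
  mids <- (nodes[seg_lo, , drop = FALSE] + nodes[seg_hi, , drop = FALSE]) / 2
  bdist <- dist_to_polyline(mids, rbind(polygon, polygon[1, ]))
  on_boundary <- bdist <= 1e-6 * max(1, max(abs(polygon)))
  # clipping a concave polygon can leave zero-measure "bridge" segments along
  # a bisector line that cross a concavity notch (outside the polygon); flag
  # segment insidedness so such artifacts can be dropped downstream
  inside <- on_boundary | points_in_polygon(mids, polygon, tol = 0)
  # interior ridge sanity: appears in exactly two cells unless it touches the hull
  interior <- !on_boundary
  # assign each boundary segment to its parent polygon edge + position along it
  np <- nrow(polygon)
  parent_edge <- rep(NA_integer_, length(seg_lo))
  along <- rep(NA_real_, length(seg_lo))
  if (any(on_boundary)) {
    bm <- mids[on_boundary, , drop = FALSE]
    best <- rep(Inf, nrow(bm)); bestk <- integer(nrow(bm)); bestt <- numeric(nrow(bm))
    for (k in seq_len(np)) {
      a <- polygon[k, ]; b <- polygon[if (k == np) 1L else k + 1L, ]
      d <- dist_point_segment(bm, a, b)
      upd <- d < best
      if (any(upd)) {
        ab <- b - a
        t <- ((bm[, 1] - a[1]) * ab[1] + (bm[, 2] - a[2]) * ab[2]) / sum(ab^2)
        best[upd] <- d[upd]; bestk[upd] <- k; bestt[upd] <- t[upd]
      }
    }
    parent_edge[on_boundary] <- bestk
    along[on_boundary] <- bestt
  }
  list(
    nodes = nodes,
    cells = cells,
    segments = tibble(
      u = seg_lo, v = seg_hi, n_cells = seg_cnt,
      on_boundary = on_boundary, inside = inside,
      parent_edge = parent_edge, along = along,
      length = sqrt(rowSums((nodes[seg_hi, , drop = FALSE] - nodes[seg_lo, , drop = FALSE])^2))
    )
  )
}
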