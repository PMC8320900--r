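# Internal planar-geometry primitives. All coordinates are micrometres (μm),
# x to the right, y downward (image row direction), origin at the image top-left.

# Signed polygon area by the shoelace formula; positive for counter-clockwise
# rings in a y-down coordinate system we treat orientation abstractly and
# normalise with ensure_ccw() before any half-plane work.
polygon_area_signed <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  sum(x * ys - xs * y) / 2
}

#' Polygon area (shoelace formula)
#'
#' Absolute area of a simple polygon given as an n x 2 matrix of vertices in
#' order (first vertex not repeated).
#'
#' @param xy Numeric matrix with two columns (x, y) in μm.
#' @return Area in μm².
#' @export
polygon_area <- function(xy) {
  xy <- as_vertex_matrix(xy)
  abs(polygon_area_signed(xy))
}

as_vertex_matrix <- function(xy) {
  xy <- as.matrix(xy)
  stopifnot(ncol(xy) == 2, nrow(xy) >= 3, all(is.finite(xy)))
  storage.mode(xy) <- "double"
  unname(xy)
}

ensure_ccw <- function(xy) {
  if (polygon_area_signed(xy) < 0) xy[rev(seq_len(nrow(xy))), , drop = FALSE] else xy
}

polygon_centroid <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  cr <- x * ys - xs * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps) return(colMeans(xy))
  c(sum((x + xs) * cr), sum((y + ys) * cr)) / (6 * a)
}

polygon_edge_lengths <- function(xy) {
  nxt <- rbind(xy[-1, , drop = FALSE], xy[1, , drop = FALSE])
  sqrt(rowSums((nxt - xy)^2))
}

# Ray-casting point-in-polygon, vectorised over query points.
# Points within `tol` of the boundary count as inside.
points_in_polygon <- function(pts, poly, tol = 1e-9) {
  pts <- matrix(as.numeric(pts), ncol = 2)
  n <- nrow(poly)
  px <- pts[, 1]; py <- pts[, 2]
  inside <- rep(FALSE, nrow(pts))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  if (tol > 0) inside | (dist_to_polyline(pts, rbind(poly, poly[1, ])) <= tol) else inside
}

# Distance from each point to a polyline (open chain of vertices).
dist_to_polyline <- function(pts, chain) {
  pts <- matrix(as.numeric(pts), ncol = 2)
  best <- rep(Inf, nrow(pts))
  for (i in seq_len(nrow(chain) - 1)) {
    best <- pmin(best, dist_point_segment(pts, chain[i, ], chain[i + 1, ]))
  }
  best
}

# Distance from points (m x 2) to the segment a-b, vectorised over points.
dist_point_segment <- function(pts, a, b) {
  ab <- b - a
  ab2 <- sum(ab^2)
  if (ab2 < .Machine$double.eps) {
    return(sqrt((pts[, 1] - a[1])^2 + (pts[, 2] - a[2])^2))
  }
  t <- ((pts[, 1] - a[1]) * ab[1] + (pts[, 2] - a[2]) * ab[2]) / ab2
  t <- pmin(1, pmax(0, t))
  dx <- a[1] + t * ab[1] - pts[, 1]
  dy <- a[2] + t * ab[2] - pts[, 2]
  sqrt(dx * dx + dy * dy)
}

# Sutherland-Hodgman clip of a convex/simple polygon against the half-plane
# {x : n . x <= c}. Returns a (possibly empty) vertex matrix.
clip_halfplane <- function(poly, nvec, cval, eps = 1e-12) {
  m <- nrow(poly)
  if (m == 0L) return(poly)
  s <- poly %*% nvec - cval
  scale <- max(1, abs(cval))
  keep <- s <= eps * scale
  if (all(keep)) return(poly)
  if (!any(keep)) return(poly[0, , drop = FALSE])
  out <- matrix(0, m + 4L, 2L)
  k <- 0L
  for (i in seq_len(m)) {
    j <- if (i == m) 1L else i + 1L
    si <- s[i]; sj <- s[j]
    if (keep[i]) {
      k <- k + 1L; out[k, ] <- poly[i, ]
      if (!keep[j]) {
        t <- si / (si - sj)
        k <- k + 1L; out[k, ] <- poly[i, ] + t * (poly[j, ] - poly[i, ])
      }
    } else if (keep[j]) {
      t <- si / (si - sj)
      k <- k + 1L; out[k, ] <- poly[i, ] + t * (poly[j, ] - poly[i, ])
    }
  }
  out <- out[seq_len(k), , drop = FALSE]
  # drop consecutive duplicates born from vertices lying on the clip line
  if (nrow(out) > 1) {
    nxt <- rbind(out[-1, , drop = FALSE], out[1, , drop = FALSE])
    dup <- rowSums((nxt - out)^2) < (1e-18 * scale^2)
    out <- out[!dup, , drop = FALSE]
  }
  out
}

# Inward offset (erosion) of a CONVEX polygon by distance e: intersect the
# half-planes of each edge shifted inward. Returns NULL if the polygon vanishes.
erode_convex_polygon <- function(poly, e) {
  poly <- ensure_ccw(poly)
  if (e <= 0) return(poly)
  out <- poly
  n <- nrow(poly)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    d <- poly[j, ] - poly[i, ]
    len <- sqrt(sum(d^2))
    if (len < .Machine$double.eps) next
    # outward normal of a CCW edge (y-down convention cancels out: we pick the
    # normal pointing away from the centroid)
    nv <- c(d[2], -d[1]) / len
    if (sum(nv * (polygon_centroid(poly) - poly[i, ])) > 0) nv <- -nv
    cval <- sum(nv * poly[i, ]) - e
    out <- clip_halfplane(out, nv, cval)
    if (nrow(out) < 3) return(NULL)
  }
  out
}

# Proper intersection test for segments p1-p2 and p3-p4 (shared endpoints and
# collinear touching do not count).
segments_cross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2); d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  ((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
    ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))
}

# Interior overlap between two simple polygons: any vertex strictly inside the
# other, or any proper edge crossing. Shared boundaries do not overlap.
polygons_overlap <- function(a, b, tol = 1e-9) {
  strictly_in <- function(pts, poly) {
    inside <- points_in_polygon(pts, poly, tol = 0)
    inside & dist_to_polyline(pts, rbind(poly, poly[1, ])) > tol
  }
  if (any(strictly_in(a, b)) || any(strictly_in(b, a))) return(TRUE)
  na <- nrow(a); nb <- nrow(b)
  for (i in seq_len(na)) {
    i2 <- if (i == na) 1L else i + 1L
    for (j in seq_len(nb)) {
      j2 <- if (j == nb) 1L else j + 1L
      if (segments_cross(a[i, ], a[i2, ], b[j, ], b[j2, ])) return(TRUE)
    }
  }
  FALSE
}

polyline_length <- function(chain) {
  if (nrow(chain) < 2) return(0)
  sum(sqrt(rowSums((chain[-1, , drop = FALSE] - chain[-nrow(chain), , drop = FALSE])^2)))
}

# Point at arclength s along an open polyline, with local unit tangent.
polyline_point_at <- function(chain, s) {
  seg <- chain[-1, , drop = FALSE] - chain[-nrow(chain), , drop = FALSE]
  lens <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(lens))
  s <- min(max(s, 0), cum[length(cum)])
  i <- max(1L, findInterval(s, cum, rightmost.closed = TRUE))
  i <- min(i, nrow(chain) - 1L)
  t <- if (lens[i] > 0) (s - cum[i]) / lens[i] else 0
  list(
    point = chain[i, ] + t * seg[i, ],
    tangent = if (lens[i] > 0) seg[i, ] / lens[i] else c(1, 0)
  )
}

# Merge near-coincident 2D points (tolerance in μm) with a hash grid; returns
# integer cluster ids and representative coordinates (first member).
snap_points <- function(pts, tol = 1e-6) {
  n <- nrow(pts)
  cell <- floor(pts / (2 * tol) + 0.5)
  key <- paste(cell[, 1], cell[, 2])
  # candidate neighbours: same or adjacent grid cell
  id <- integer(n)
  reps <- matrix(0, n, 2)
  nrep <- 0L
  buckets <- new.env(parent = emptyenv(), hash = TRUE)
  offs <- expand.grid(dx = -1:1, dy = -1:1)
  for (i in seq_len(n)) {
    found <- 0L
    for (k in seq_len(9L)) {
      kk <- paste(cell[i, 1] + offs$dx[k], cell[i, 2] + offs$dy[k])
      cand <- buckets[[kk]]
      if (!is.null(cand)) {
        for (r in cand) {
          if (max(abs(pts[i, ] - reps[r, ])) <= tol) { found <- r; break }
        }
      }
      if (found > 0L) break
    }
    if (found == 0L) {
      nrep <- nrep + 1L
      reps[nrep, ] <- pts[i, ]
      buckets[[key[i]]] <- c(buckets[[key[i]]], nrep)
      found <- nrep
    }
    id[i] <- found
  }
  list(id = id, coords = reps[seq_len(nrep), , drop = FALSE])
}
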