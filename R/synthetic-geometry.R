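# Synthetic alveolar fields, corner-vessel skeletons and diameter
# time-courses: the ground-truthed stand-ins for the experimental inputs.

is_convex_polygon <- function(poly) {
  n <- nrow(poly)
  s <- 0
  for (i in seq_len(n)) {
    a <- poly[i, ]; b <- poly[(i %% n) + 1, ]; c <- poly[((i + 1) %% n) + 1, ]
    cr <- (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
    if (abs(cr) < 1e-12) next
    if (s == 0) s <- sign(cr) else if (sign(cr) != s) return(FALSE)
  }
  TRUE
}

sample_points_in_polygon <- function(n, poly, margin = 0) {
  bb <- apply(poly, 2, range)
  out <- matrix(0, 0, 2)
  guard <- 0L
  while (nrow(out) < n) {
    m <- max(2L * (n - nrow(out)), 16L)
    cand <- cbind(runif(m, bb[1, 1], bb[2, 1]), runif(m, bb[1, 2], bb[2, 2]))
    ok <- points_in_polygon(cand, poly, tol = 0)
    if (margin > 0) {
      ok <- ok & dist_to_polyline(cand, rbind(poly, poly[1, ])) > margin
    }
    out <- rbind(out, cand[ok, , drop = FALSE])
    guard <- guard + 1L
    if (guard > 1000L) abort("could not place points inside the polygon (margin too large?)")
  }
  out[seq_len(n), , drop = FALSE]
}

#' Generate a synthetic alveolar field inside a region of interest
#'
#' Partitions a convex ROI into `n_alveoli` Voronoi cells of uniformly sampled
#' seed points and erodes each cell inward by `erosion_um`, leaving
#' interstitial gaps between alveoli (the erosion distance is the synthetic
#' interstitial-thickness knob).
#'
#' @param n_alveoli Number of alveoli (>= 1).
#' @param roi Convex ROI polygon vertex matrix (μm).
#' @param erosion_um Inward offset of each cell (μm); 0 gives a gapless
#'   partition with zero interstitial area.
#' @param seed Integer seed; fixes the field exactly.
#' @return An `alveolar_field` list: `roi_um`, `alveoli_um` (list of polygon
#'   matrices), `alveolar_area_um2`, `interstitial_area_um2` (analytic,
#'   ROI area minus total alveolar area).
#' @export
generate_alveolar_field <- function(n_alveoli, roi, erosion_um = 15, seed = 1L) {
  roi <- ensure_ccw(as_vertex_matrix(roi))
  if (n_alveoli < 1) abort("n_alveoli must be >= 1")
  if (!is_convex_polygon(roi)) abort("roi must be a convex polygon")
  if (erosion_um < 0) abort("erosion_um must be non-negative")
  cells <- local_rng(seed, {
    pts <- sample_points_in_polygon(n_alveoli, roi, margin = min(erosion_um, sqrt(polygon_area(roi)) / 20))
    clipped_voronoi(pts, roi)
  })
  alveoli <- lapply(cells, erode_convex_polygon, e = erosion_um)
  if (any(vapply(alveoli, is.null, logical(1))))
    abort("roi too small to host n_alveoli at this erosion: a cell vanished")
  areas <- vapply(alveoli, polygon_area, numeric(1))
  structure(list(
    roi_um = roi,
    alveoli_um = alveoli,
    alveolar_area_um2 = sum(areas),
    interstitial_area_um2 = polygon_area(roi) - sum(areas)
  ), class = "alveolar_field")
}

#' @export
print.alveolar_field <- function(x, ...) {
  cat(sprintf("<alveolar_field> %d alveoli, ROI %.0f um^2, interstitial %.0f um^2 (%.1f%%)\n",
              length(x$alveoli_um), polygon_area(x$roi_um), x$interstitial_area_um2,
              100 * x$interstitial_area_um2 / polygon_area(x$roi_um)))
  invisible(x)
}

#' Generate a corner-vessel skeleton for one alveolar capillary unit
#'
#' Builds a closed polygon of corner vessels by placing `n_corner_junctions`
#' junctions at jittered angular positions on a perturbed convex outline, then
#' rescaling affinely so the mean corner length equals `mean_corner_length`
#' exactly. With `corner_length_sd = 0` the skeleton is a regular polygon.
#' Arteriolar inlet junctions and venular outlet junctions are placed on
#' opposite sides of the cycle.
#'
#' @param n_corner_junctions Number of corner junctions (>= 3; >= 6 for
#'   realistic alveoli).
#' @param mean_corner_length Target mean corner vessel length (μm).
#' @param corner_length_sd Spread of corner lengths (μm); drives the angular
#'   and radial jitter of the outline.
#' @param corner_diameter_range Corner diameters are sampled uniformly in this
#'   band (μm); default the 10-50 μm corner class.
#' @param n_inlets,n_outlets Number of inlet / outlet junctions.
#' @param seed Integer seed.
#' @return An `acu_network` holding only the corner cycle, with designated
#'   inlet/outlet junction nodes.
#' @export
generate_acu_skeleton <- function(n_corner_junctions = 8, mean_corner_length = 273,
                                  corner_length_sd = 76,
                                  corner_diameter_range = c(10, 50),
                                  n_inlets = 1, n_outlets = 1, seed = 1L) {
  n <- as.integer(n_corner_junctions)
  if (n < 3) abort("need at least 3 corner junctions")
  if (mean_corner_length <= 0) abort("mean_corner_length must be positive")
  if (corner_length_sd < 0) abort("corner_length_sd must be non-negative")
  cv <- corner_length_sd / mean_corner_length
  if (cv > 0.6) abort("infeasible length distribution: sd too large relative to mean (negative lengths after clipping)")
  if (n_inlets + n_outlets > n) abort("more inlets/outlets than junctions")
  poly <- local_rng(seed, {
    base_ang <- 2 * pi * (seq_len(n) - 1) / n
    ang <- base_ang + if (cv > 0) runif(n, -0.35, 0.35) * 2 * pi / n else 0
    z <- if (cv > 0) pmax(-2, pmin(2, rnorm(n))) else numeric(n)
    r <- 1 + 1.2 * cv * z
    if (any(r <= 0.05)) abort("infeasible length distribution: negative radius after clipping")
    cbind(r * cos(ang), r * sin(ang))
  })
  m0 <- mean(polygon_edge_lengths(poly))
  poly <- poly * (mean_corner_length / m0)
  # shift into the positive quadrant (image-like coordinates)
  poly <- sweep(poly, 2, apply(poly, 2, min)) + mean_corner_length / 4
  lens <- polygon_edge_lengths(poly)
  diam <- local_rng(child_seed(seed, 2), runif(n, corner_diameter_range[1], corner_diameter_range[2]))
  nodes <- tibble(id = seq_len(n), x_um = poly[, 1], y_um = poly[, 2],
                  kind = "corner_junction")
  edges <- tibble(id = seq_len(n), from = seq_len(n), to = c(2:n, 1),
                  kind = "corner", diameter_um = diam, length_um = lens,
                  corner_id = seq_len(n))
  inlets <- seq_len(n_inlets)
  outlets <- ((seq_len(n_outlets) - 1 + floor(n / 2)) %% n) + 1
  if (length(intersect(inlets, outlets)) > 0)
    abort("inlet and outlet junctions overlap; reduce their counts")
  acu_network(nodes, edges, inlets = inlets, outlets = outlets,
              polygon = poly, barrier_um = 6.5)
}

#' Programmed vessel-diameter time-course
#'
#' Emulates the observed hypoxic responses of sub-100-μm distribution vessels:
#' `"constrict_reopen"` halves the diameter at 30 min and recovers to baseline
#' from 80 min on; `"closing"` reaches complete closure at 30 min before
#' reopening; `"stable"` stays at baseline.
#'
#' @param baseline_um Baseline diameter (μm, > 0).
#' @param pattern One of `"constrict_reopen"`, `"stable"`, `"closing"`.
#' @param timepoints Sorted acquisition times in minutes (must include 0).
#' @param jitter Multiplicative noise s.d. applied to non-baseline values
#'   (0 = deterministic course).
#' @param seed Integer seed for the jitter.
#' @return Tibble with `timepoint_min`, `diameter_um`.
#' @export
generate_diameter_timecourse <- function(baseline_um,
                                         pattern = c("constrict_reopen", "stable", "closing"),
                                         timepoints = c(0, 30, 120), jitter = 0, seed = NULL) {
  pattern <- match.arg(pattern)
  if (baseline_um <= 0) abort("baseline_um must be positive")
  if (is.unsorted(timepoints)) abort("timepoints must be sorted")
  knots <- switch(pattern,
    stable = list(t = c(0, 1e6), f = c(1, 1)),
    constrict_reopen = list(t = c(0, 30, 80, 1e6), f = c(1, 0.5, 1, 1)),
    closing = list(t = c(0, 30, 80, 1e6), f = c(1, 0, 0.95, 0.95))
  )
  f <- approx(knots$t, knots$f, xout = timepoints, rule = 2)$y
  val <- baseline_um * f
  if (jitter > 0) {
    fac <- local_rng(seed, pmax(0, 1 + rnorm(length(val), sd = jitter)))
    fac[timepoints == 0] <- 1
    val <- val * fac
    # recovery phase stays recovered (>= 95% of baseline) under jitter
    rec <- timepoints >= 80 & pattern == "constrict_reopen"
    val[rec] <- pmax(val[rec], 0.95 * baseline_um)
  }
  tibble(timepoint_min = as.numeric(timepoints), diameter_um = val)
}
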