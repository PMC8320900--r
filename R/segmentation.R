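# Vessel diameter measurement from transect intensity profiles, vessel
# classification, interstitial area bookkeeping and time-series normalisation.
#
# The border rule: the lumen images dark; moving from the profile's interior
# minimum outward, the vessel border is the position of maximal magnitude of
# the moving-average grey-level gradient on each flank, refined to sub-sample
# precision by parabolic interpolation of the gradient peak.

# Bilinear grey-level interpolation at physical positions (μm). Positions must
# lie within half a pixel of the image interior.
interp_image <- function(img, pts) {
  sc <- img$pixel_scale
  cx <- pts[, 1] / sc + 0.5   # fractional column index (pixel centres at i - 0.5)
  ry <- pts[, 2] / sc + 0.5
  nr <- nrow(img$pixels); nc <- ncol(img$pixels)
  cx <- pmin(pmax(cx, 1), nc); ry <- pmin(pmax(ry, 1), nr)
  c0 <- pmin(floor(cx), nc - 1); r0 <- pmin(floor(ry), nr - 1)
  fx <- cx - c0; fy <- ry - r0
  p <- img$pixels
  v00 <- p[cbind(r0, c0)];     v01 <- p[cbind(r0, c0 + 1)]
  v10 <- p[cbind(r0 + 1, c0)]; v11 <- p[cbind(r0 + 1, c0 + 1)]
  (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11)
}

#' Sample an intensity transect across an image
#'
#' @param img A [micro_image()].
#' @param p0,p1 Transect endpoints in μm (length-2 vectors).
#' @param step Sampling step in μm; defaults to half a pixel.
#' @return A `transect`: tibble with `s_um` (position along the transect) and
#'   `intensity`, plus endpoint/step attributes.
#' @export
transect_profile <- function(img, p0, p1, step = img$pixel_scale / 2) {
  stopifnot(inherits(img, "micro_image"))
  p0 <- as.numeric(p0); p1 <- as.numeric(p1)
  len <- sqrt(sum((p1 - p0)^2))
  if (len <= 0) abort("transect endpoints must be distinct")
  s <- seq(0, len, by = step)
  dirv <- (p1 - p0) / len
  pts <- cbind(p0[1] + s * dirv[1], p0[2] + s * dirv[2])
  # clip to the sampleable interior of the image
  sc <- img$pixel_scale
  ok <- pts[, 1] >= sc / 2 & pts[, 1] <= (ncol(img$pixels) - 0.5) * sc &
        pts[, 2] >= sc / 2 & pts[, 2] <= (nrow(img$pixels) - 0.5) * sc
  if (sum(ok) < 5) abort("transect lies outside the image")
  out <- tibble(s_um = s[ok], intensity = interp_image(img, pts[ok, , drop = FALSE]))
  structure(out, class = c("transect", class(out)), step_um = step, p0 = p0, p1 = p1)
}

#' Locate the lumen borders on a transect profile
#'
#' Smooths the profile with a moving average, finds its interior minimum, and
#' returns on each flank the position of maximal gradient magnitude (the sharp
#' grey-level change marking the vessel border), refined to sub-sample
#' precision. The detection is affine-invariant in grey levels up to the
#' contrast threshold.
#'
#' @param t A `transect` from [transect_profile()], or any tibble with `s_um`
#'   and `intensity` at a uniform step.
#' @param window Moving-average window in μm; defaults to 3 samples.
#' @param contrast_threshold Minimal grey-level depth of the interior minimum
#'   below the flanking surround for a lumen to be declared present.
#' @return List with `left_um`, `right_um`, `width_um`.
#' @export
detect_lumen_borders <- function(t, window = NULL, contrast_threshold = 15) {
  s <- t$s_um; y <- t$intensity
  n <- length(y)
  step <- if (n > 1) stats::median(diff(s)) else abort("empty profile")
  k <- if (is.null(window)) 3L else max(1L, round(window / step))
  if (k %% 2 == 0) k <- k + 1L
  if (n < k + 4) abort("profile shorter than the smoothing window")
  sm <- moving_average(y, k)
  im <- which.min(sm)
  flank <- max(3L, ceiling(0.25 * n))
  left_lvl <- stats::median(sm[seq_len(min(flank, n))])
  right_lvl <- stats::median(sm[seq(max(1, n - flank + 1), n)])
  depth <- min(left_lvl, right_lvl) - sm[im]
  if (im <= 1 || im >= n || depth < contrast_threshold) {
    abort("no vessel on transect: no interior minimum darker than the surround by the contrast threshold",
          class = "acuflow_no_vessel")
  }
  g <- diff(sm) / step            # gradient at midpoints s + step/2
  smid <- s[-n] + step / 2
  il <- which.max(abs(g[seq_len(im - 1)]))
  ir_rel <- which.max(abs(g[im:(n - 1)]))
  ir <- im - 1L + ir_rel
  left_um <- peak_subsample(smid, abs(g), il, step)
  right_um <- peak_subsample(smid, abs(g), ir, step)
  list(left_um = left_um, right_um = right_um, width_um = right_um - left_um)
}

moving_average <- function(y, k) {
  if (k <= 1) return(y)
  n <- length(y)
  h <- (k - 1L) %/% 2L
  ypad <- c(rep(y[1], h), y, rep(y[n], h))
  as.numeric(stats::filter(ypad, rep(1 / k, k), sides = 2))[(h + 1):(h + n)]
}

# Parabolic (3-point) sub-sample refinement of a peak of |gradient|.
peak_subsample <- function(x, y, j, step) {
  if (j <= 1 || j >= length(y)) return(x[j])
  denom <- y[j - 1] - 2 * y[j] + y[j + 1]
  if (abs(denom) < .Machine$double.eps) return(x[j])
  d <- 0.5 * (y[j - 1] - y[j + 1]) / denom
  x[j] + max(-1, min(1, d)) * step
}

#' Measure a vessel diameter from evenly spaced transects
#'
#' Places `n_transects` transects perpendicular to the local centerline tangent
#' at evenly spaced stations, measures the lumen width on each via
#' [detect_lumen_borders()], and averages. If at least `closed_fraction` of
#' the transects find no lumen the vessel is declared closed (diameter 0).
#'
#' @param img A [micro_image()].
#' @param centerline_um k x 2 polyline matrix (μm) inside the image.
#' @param n_transects Number of transects (default 4).
#' @param expected_um Prior diameter guess setting the transect half-length
#'   (2 x expected); default 100 μm.
#' @param window Moving-average window (μm) for border detection.
#' @param contrast_threshold See [detect_lumen_borders()].
#' @param closed_fraction Fraction of failed transects that declares closure.
#' @param vessel_id,timepoint_min Identifiers copied into the result.
#' @return One-row tibble: `vessel_id`, `timepoint_min`, `diameter_um`,
#'   `n_transects` (transects that found a lumen), `closed`.
#' @export
measure_diameter <- function(img, centerline_um, n_transects = 4, expected_um = 100,
                             window = NULL, contrast_threshold = 15,
                             closed_fraction = 0.75, vessel_id = NA_integer_,
                             timepoint_min = img$timepoint) {
  stopifnot(inherits(img, "micro_image"), n_transects >= 1)
  cl <- matrix(as.numeric(centerline_um), ncol = 2)
  sc <- img$pixel_scale
  wmax <- c(ncol(img$pixels), nrow(img$pixels)) * sc
  if (any(cl < 0) || any(cl[, 1] > wmax[1]) || any(cl[, 2] > wmax[2]))
    abort("centerline lies outside the image bounds")
  total <- polyline_length(cl)
  if (total <= 0) abort("degenerate centerline")
  half <- 2 * expected_um
  stations <- (seq_len(n_transects) - 0.5) / n_transects * total
  widths <- rep(NA_real_, n_transects)
  for (i in seq_len(n_transects)) {
    loc <- polyline_point_at(cl, stations[i])
    nv <- c(-loc$tangent[2], loc$tangent[1])
    p0 <- loc$point - half * nv
    p1 <- loc$point + half * nv
    res <- tryCatch(
      detect_lumen_borders(transect_profile(img, p0, p1),
                           window = window, contrast_threshold = contrast_threshold),
      acuflow_no_vessel = function(e) NULL,
      error = function(e) NULL
    )
    if (!is.null(res)) widths[i] <- res$width_um
  }
  failed <- sum(is.na(widths))
  closed <- failed / n_transects >= closed_fraction
  tibble(
    vessel_id = vessel_id,
    timepoint_min = timepoint_min,
    diameter_um = if (closed) 0 else mean(widths, na.rm = TRUE),
    n_transects = n_transects - failed,
    closed = closed
  )
}

#' Measure all annotated vessels on an image
#'
#' Tabular wrapper over [measure_diameter()].
#'
#' @param img A [micro_image()].
#' @param annotations Tibble with `vessel_id` and a `centerline_um`
#'   list-column; an optional `expected_um` column sets per-vessel transect
#'   half-lengths.
#' @param ... Passed to [measure_diameter()].
#' @return Tibble with one row per vessel.
#' @export
measure_vessels <- function(img, annotations, ...) {
  annotations <- as_tibble(annotations)
  expected <- annotations$expected_um %||% rep(100, nrow(annotations))
  purrr::pmap(list(annotations$vessel_id, annotations$centerline_um, expected),
              function(idv, cl, ex) measure_diameter(img, cl, expected_um = ex, vessel_id = idv, ...)) |>
    bind_rows()
}

#' Classify a vessel by its baseline diameter
#'
#' Class bands follow the imaged vessel districts: corner vessels 10-50 μm,
#' small distribution vessels 50-100 μm, large distribution vessels
#' 100-250 μm (boundaries assigned to the larger class). Diameters outside
#' 10-250 μm (e.g. the 5-8 μm septal capillaries, not directly imageable) are
#' `"unclassified"`. Class membership is fixed at baseline: constriction below
#' 50 μm does not reclassify a distribution vessel.
#'
#' @param baseline_diameter Baseline diameter(s) in μm, positive.
#' @return Character vector of class labels.
#' @export
classify_vessel <- function(baseline_diameter) {
  if (any(baseline_diameter <= 0)) abort("baseline diameter must be positive")
  dplyr::case_when(
    baseline_diameter < 10 | baseline_diameter > 250 ~ "unclassified",
    baseline_diameter >= 100 ~ "distribution_large",
    baseline_diameter >= 50 ~ "distribution_small",
    TRUE ~ "corner"
  )
}

#' Interstitial area of a region of interest
#'
#' The peri-alveolar interstitial space is the ROI area minus the summed
#' alveolar areas (shoelace formula). Alveoli must lie inside the ROI and be
#' pairwise disjoint.
#'
#' @param roi ROI polygon matrix (μm) or an `alveolar_field`.
#' @param alveoli List of alveolar polygon matrices (μm); taken from the field
#'   when `roi` is an `alveolar_field`.
#' @return One-row tibble: `roi_area_um2`, `alveolar_area_um2`,
#'   `interstitial_area_um2`.
#' @export
estimate_interstitial <- function(roi, alveoli = NULL) {
  if (inherits(roi, "alveolar_field")) {
    alveoli <- roi$alveoli_um
    roi <- roi$roi_um
  }
  roi <- as_vertex_matrix(roi)
  alveoli <- alveoli %||% list()
  tolm <- 1e-6 * max(1, max(abs(roi)))
  for (a in alveoli) {
    if (!all(points_in_polygon(as_vertex_matrix(a), roi, tol = tolm)))
      abort("alveolus extends outside the ROI")
  }
  if (length(alveoli) > 1) {
    for (i in seq_len(length(alveoli) - 1)) {
      for (j in seq(i + 1, length(alveoli))) {
        if (polygons_overlap(as_vertex_matrix(alveoli[[i]]), as_vertex_matrix(alveoli[[j]]), tol = tolm))
          abort("alveolar polygons overlap")
      }
    }
  }
  ra <- polygon_area(roi)
  aa <- sum(vapply(alveoli, polygon_area, numeric(1)))
  tibble(roi_area_um2 = ra, alveolar_area_um2 = aa,
         interstitial_area_um2 = ra - aa)
}

#' Normalise diameter series to baseline
#'
#' Divides each vessel's diameters by its baseline (t = 0) value; closed
#' timepoints map to relative diameter 0.
#'
#' @param measurements Tibble with `timepoint_min`, `diameter_um` and
#'   optionally `vessel_id` (grouped per vessel when present).
#' @return The input with a `relative_diameter` column.
#' @export
normalize_series <- function(measurements) {
  m <- as_tibble(measurements)
  if (!"vessel_id" %in% names(m)) m$vessel_id <- 1L
  norm_one <- function(df) {
    base <- df$diameter_um[df$timepoint_min == 0]
    if (length(base) != 1 || base <= 0)
      abort("missing baseline: each vessel needs one t = 0 measurement with diameter > 0")
    df$relative_diameter <- df$diameter_um / base
    df
  }
  m |> group_by(.data$vessel_id) |> dplyr::group_modify(~ norm_one(.x)) |> ungroup()
}

#' Read a vessel/alveolus annotation file
#'
#' Annotations are JSON with μm coordinates:
#' `{"vessels": [{"id": 1, "centerline_um": [[x, y], ...]}, ...],
#'   "alveoli": [{"id": 1, "polygon_um": [[x, y], ...]}, ...],
#'   "roi_um": [[x, y], ...]}`.
#'
#' @param path JSON file path (or a JSON string).
#' @return List with `vessels` (tibble: `vessel_id`, `centerline_um`
#'   list-column, ready for [measure_vessels()]), `alveoli` (list of polygon
#'   matrices) and `roi_um` (polygon matrix), any of which may be absent.
#' @export
read_annotations <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  as_mat <- function(x) {
    if (is.null(x)) return(NULL)
    m <- if (is.list(x)) do.call(rbind, x) else as.matrix(x)
    storage.mode(m) <- "double"
    unname(m)
  }
  vessels <- NULL
  if (!is.null(obj$vessels)) {
    vessels <- tibble(
      vessel_id = obj$vessels$id,
      centerline_um = lapply(obj$vessels$centerline_um, as_mat)
    )
  }
  alveoli <- NULL
  if (!is.null(obj$alveoli)) {
    alveoli <- lapply(obj$alveoli$polygon_um, as_mat)
    names(alveoli) <- obj$alveoli$id
  }
  list(vessels = vessels, alveoli = alveoli, roi_um = as_mat(obj$roi_um))
}
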