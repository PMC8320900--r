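# Border detection, diameter measurement, classification, interstitial area,
# and baseline normalisation.

# samples of an ideal dark step band [a, b] at half-sample offsets so the true
# edges fall exactly between samples
step_profile <- function(a = 20, b = 92, lo = 50, hi = 200, step = 1, len = 120) {
  s <- seq(step / 2, len, by = step)
  tibble::tibble(s_um = s, intensity = ifelse(s > a & s < b, lo, hi))
}

test_that("border detection recovers ideal step edges exactly with no smoothing", {
  res <- detect_lumen_borders(step_profile(), window = 0)
  expect_equal(res$left_um, 20, tolerance = 1e-9)
  expect_equal(res$right_um, 92, tolerance = 1e-9)
  expect_equal(res$width_um, 72, tolerance = 1e-9)
})

test_that("border detection recovers a blurred step within one pixel", {
  # analytically blurred step (sigma = 5 um), sampled at half-pixel steps
  sigma <- 5; a <- 20; b <- 92
  s <- seq(0.25, 120, by = 0.5)
  inten <- 200 - 150 * (pnorm((s - a) / sigma) - pnorm((s - b) / sigma))
  res <- detect_lumen_borders(tibble::tibble(s_um = s, intensity = inten),
                              window = 3 * 7.2)
  expect_equal(res$width_um, 72, tolerance = 7.2)
  # the gradient of a symmetrically blurred step peaks at the edge itself
  expect_equal(res$left_um, 20, tolerance = 1)
  expect_equal(res$right_um, 92, tolerance = 1)
})

test_that("flat profiles raise the no-vessel condition", {
  flat <- tibble::tibble(s_um = seq(0.5, 100, by = 1), intensity = 200)
  expect_error(detect_lumen_borders(flat), class = "acuflow_no_vessel")
})

test_that("border positions are invariant to affine grey-level changes", {
  sigma <- 4
  s <- seq(0.25, 110, by = 0.5)
  inten <- 190 - 140 * (pnorm((s - 30) / sigma) - pnorm((s - 75) / sigma))
  base <- detect_lumen_borders(tibble::tibble(s_um = s, intensity = inten),
                               contrast_threshold = 10)
  scaled <- detect_lumen_borders(tibble::tibble(s_um = s, intensity = 0.8 * inten + 30),
                                 contrast_threshold = 10)
  expect_equal(scaled$left_um, base$left_um, tolerance = 1e-9)
  expect_equal(scaled$right_um, base$right_um, tolerance = 1e-9)
})

test_that("diameter measurement averages transects and recovers ground truth", {
  sc <- 7.2
  sp <- synth_image_spec(
    image_size = c(60, 60), pixel_scale = sc,
    vessels = tibble::tibble(
      centerline_um = list(rbind(c(40, 210), c(60 * sc - 40, 220))),
      width_um = 72, grey = 60
    ),
    background_grey = 200, noise_sd = 5, blur_sigma_um = 7.2, seed = 4
  )
  out <- generate_vessel_image(sp)
  m <- measure_diameter(out$image, out$truth$centerline_um[[1]], expected_um = 72)
  expect_false(m$closed)
  expect_equal(m$n_transects, 4)
  expect_equal(m$diameter_um, 72, tolerance = 7.2)
  # the reported diameter is the arithmetic mean of the per-transect widths
  cl <- out$truth$centerline_um[[1]]
  total <- acuflow:::polyline_length(cl)
  widths <- vapply(((1:4) - 0.5) / 4 * total, function(st) {
    loc <- acuflow:::polyline_point_at(cl, st)
    nv <- c(-loc$tangent[2], loc$tangent[1])
    detect_lumen_borders(
      transect_profile(out$image, loc$point - 144 * nv, loc$point + 144 * nv))$width_um
  }, numeric(1))
  expect_equal(m$diameter_um, mean(widths), tolerance = 1e-9)
})

test_that("occluded vessels are flagged closed with diameter zero", {
  sc <- 7.2
  img <- micro_image(matrix(200, 50, 50), pixel_scale = sc)
  m <- measure_diameter(img, rbind(c(50, 180), c(300, 180)))
  expect_true(m$closed)
  expect_equal(m$diameter_um, 0)
  expect_error(measure_diameter(img, rbind(c(-50, 0), c(100, 0))), "outside")
})

test_that("repeated-measurement variance does not grow with transect count", {
  sc <- 7.2
  est <- function(n_tr) {
    vapply(1:25, function(s) {
      sp <- synth_image_spec(
        image_size = c(50, 50), pixel_scale = sc,
        vessels = tibble::tibble(
          centerline_um = list(rbind(c(30, 180), c(330, 180))),
          width_um = 80, grey = 70
        ),
        background_grey = 200, noise_sd = 20, blur_sigma_um = 7.2, seed = s
      )
      img <- generate_vessel_image(sp)$image
      measure_diameter(img, rbind(c(30, 180), c(330, 180)), n_transects = n_tr,
                       expected_um = 80)$diameter_um
    }, numeric(1))
  }
  v1 <- stats::var(est(1))
  v4 <- stats::var(est(4))
  expect_lte(v4, v1 * 1.05)
})

test_that("vessel classes follow the baseline diameter bands", {
  expect_equal(classify_vessel(30), "corner")
  expect_equal(classify_vessel(150), "distribution_large")
  expect_equal(classify_vessel(6), "unclassified")
  expect_equal(classify_vessel(c(50, 100, 250, 251, 10)),
               c("distribution_small", "distribution_large", "distribution_large",
                 "unclassified", "corner"))
  expect_error(classify_vessel(0), "positive")
})

test_that("interstitial area is the exact ROI-minus-alveoli difference", {
  roi <- rbind(c(0, 0), c(1000, 0), c(1000, 1000), c(0, 1000))
  alv <- rbind(c(100, 100), c(600, 100), c(600, 600), c(100, 600))
  est <- estimate_interstitial(roi, list(alv))
  expect_equal(est$interstitial_area_um2, 750000)
  expect_equal(estimate_interstitial(roi, list())$interstitial_area_um2, 1e6)
  shifted <- alv + 300
  expect_error(estimate_interstitial(roi, list(alv, shifted)), "overlap")
  expect_error(estimate_interstitial(roi, list(alv + 600)), "outside")
})

test_that("series normalisation maps closures to zero and needs a baseline", {
  m <- tibble::tibble(timepoint_min = c(0, 30, 120), diameter_um = c(80, 40, 80))
  expect_equal(normalize_series(m)$relative_diameter, c(1, 0.5, 1))
  m2 <- tibble::tibble(timepoint_min = c(0, 30, 120), diameter_um = c(80, 0, 76))
  expect_equal(normalize_series(m2)$relative_diameter, c(1, 0, 0.95))
  expect_error(normalize_series(m2[-1, ]), "baseline")
  tc <- generate_diameter_timecourse(80, "constrict_reopen", c(0, 30, 120), jitter = 0)
  norm <- normalize_series(tc)
  expect_equal(norm$relative_diameter[norm$timepoint_min == 30], 0.5)
})

test_that("annotation JSON round-trips into measurable tibbles", {
  ann <- list(
    vessels = list(list(id = 1L, centerline_um = rbind(c(10, 20), c(200, 25))),
                   list(id = 2L, centerline_um = rbind(c(30, 80), c(180, 90)))),
    alveoli = list(list(id = 1L, polygon_um = rbind(c(0, 0), c(100, 0), c(100, 100)))),
    roi_um = rbind(c(0, 0), c(300, 0), c(300, 300), c(0, 300))
  )
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(ann, path, auto_unbox = TRUE, digits = NA)
  back <- read_annotations(path)
  expect_equal(nrow(back$vessels), 2)
  expect_equal(back$vessels$centerline_um[[1]], rbind(c(10, 20), c(200, 25)))
  expect_equal(back$roi_um, ann$roi_um)
  expect_length(back$alveoli, 1)
})
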