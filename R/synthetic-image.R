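# Synthetic intravital-microscopy image generator.
#
# Emulates greyscale subpleural imagery: dark vessel lumens of known width on
# a brighter, textured parenchymal background, with optical blur. The pre-blur
# band width is the ground truth against which segmentation is scored.

#' Greyscale microscopy image container
#'
#' @param pixels Numeric matrix of grey levels in `[0, 255]` (rows = image
#'   rows, y downward).
#' @param pixel_scale Physical scale in μm/pixel (7.2 μm at the 15x
#'   magnification the pipeline targets).
#' @param timepoint Acquisition time in minutes.
#' @return A `micro_image` object.
#' @export
micro_image <- function(pixels, pixel_scale = 7.2, timepoint = 0) {
  pixels <- as.matrix(pixels)
  if (!is.numeric(pixels) || length(pixels) == 0) abort("pixels must be a non-empty numeric matrix")
  if (pixel_scale <= 0) abort("pixel_scale must be positive")
  structure(list(pixels = pixels, pixel_scale = pixel_scale, timepoint = timepoint),
            class = "micro_image")
}

#' @export
print.micro_image <- function(x, ...) {
  cat(sprintf("<micro_image> %d x %d px @ %.2f um/px (t = %s min), grey [%.0f, %.0f]\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_scale, format(x$timepoint),
              min(x$pixels), max(x$pixels)), sep = "")
  invisible(x)
}

#' Specification for a synthetic vessel image
#'
#' @param image_size `c(rows, cols)` in pixels.
#' @param pixel_scale μm per pixel.
#' @param vessels Tibble (or data frame) with one row per vessel: `width_um`,
#'   `grey` (lumen grey level), and a `centerline_um` list-column of k x 2
#'   polyline matrices in μm.
#' @param background_grey Parenchymal background grey level (must exceed every
#'   lumen grey: vessels image dark).
#' @param noise_sd Grey-level s.d. of the background texture noise, applied
#'   before optical blur.
#' @param blur_sigma_um Gaussian optical blur sigma in μm (0 disables).
#' @param seed Integer seed fixing the output bit-exactly.
#' @return A validated `synth_image_spec` list.
#' @export
synth_image_spec <- function(image_size = c(96, 96), pixel_scale = 7.2, vessels,
                             background_grey = 190, noise_sd = 8,
                             blur_sigma_um = 7.2, seed = 1L) {
  vessels <- as_tibble(vessels)
  stopifnot(all(c("centerline_um", "width_um", "grey") %in% names(vessels)))
  if (any(vessels$grey >= background_grey))
    abort("lumen grey level must be below the background grey (vessels image dark)")
  if (any(vessels$width_um <= 2 * pixel_scale))
    abort(sprintf("vessel width below resolvability: all widths must exceed 2 x pixel_scale = %.1f um",
                  2 * pixel_scale))
  structure(list(image_size = as.integer(image_size), pixel_scale = pixel_scale,
                 vessels = vessels, background_grey = background_grey,
                 noise_sd = noise_sd, blur_sigma_um = blur_sigma_um,
                 seed = as.integer(seed)),
            class = "synth_image_spec")
}

#' Render a synthetic vessel image with ground truth
#'
#' Draws each vessel as an anti-aliased dark band of constant full width along
#' its centerline, adds background texture noise, then applies Gaussian
#' optical blur. The ground truth records the exact pre-blur band widths.
#'
#' @param spec A [synth_image_spec()].
#' @return List with `image` (a [micro_image()]) and `truth`, a tibble with
#'   `vessel_id`, `width_um`, `class` (baseline diameter class) and the
#'   `centerline_um` list-column.
#' @export
generate_vessel_image <- function(spec) {
  stopifnot(inherits(spec, "synth_image_spec"))
  nr <- spec$image_size[1]; nc <- spec$image_size[2]; sc <- spec$pixel_scale
  px <- (col(matrix(0, nr, nc)) - 0.5) * sc
  py <- (row(matrix(0, nr, nc)) - 0.5) * sc
  pts <- cbind(as.vector(px), as.vector(py))
  img <- matrix(spec$background_grey, nr, nc)
  for (i in seq_len(nrow(spec$vessels))) {
    cl <- spec$vessels$centerline_um[[i]]
    w <- spec$vessels$width_um[i]
    g <- spec$vessels$grey[i]
    d <- dist_to_polyline(pts, as.matrix(cl))
    cov <- pmin(1, pmax(0, (w / 2 - d) / sc + 0.5))
    val <- spec$background_grey + cov * (g - spec$background_grey)
    img <- matrix(pmin(as.vector(img), val), nr, nc)
  }
  img <- local_rng(spec$seed, {
    out <- img + matrix(rnorm(nr * nc, sd = spec$noise_sd), nr, nc)
    out
  })
  if (spec$blur_sigma_um > 0) {
    img <- gaussian_blur(img, spec$blur_sigma_um / sc)
  }
  img <- matrix(pmin(pmax(img, 0), 255), nr, nc)
  truth <- tibble(
    vessel_id = seq_len(nrow(spec$vessels)),
    width_um = spec$vessels$width_um,
    class = classify_vessel(spec$vessels$width_um),
    centerline_um = spec$vessels$centerline_um
  )
  list(image = micro_image(img, pixel_scale = sc), truth = truth)
}

# Gaussian blur of a grey-level matrix, sigma in pixels (EBImage when present,
# with a separable fallback kernel so the generator has no hard image-stack
# dependency).
gaussian_blur <- function(img, sigma_px) {
  if (sigma_px <= 0) return(img)
  if (requireNamespace("EBImage", quietly = TRUE)) {
    return(as.matrix(EBImage::gblur(img, sigma = sigma_px, boundary = "replicate")))
  }
  r <- max(1L, ceiling(3 * sigma_px))
  k <- stats::dnorm(-r:r, sd = sigma_px); k <- k / sum(k)
  pad <- function(m, n) rbind(m[rep(1, n), , drop = FALSE], m, m[rep(nrow(m), n), , drop = FALSE])
  conv_cols <- function(m) {
    mp <- pad(m, r)
    out <- matrix(0, nrow(m), ncol(m))
    for (i in seq_along(k)) out <- out + k[i] * mp[i:(i + nrow(m) - 1L), , drop = FALSE]
    out
  }
  t(conv_cols(t(conv_cols(img))))
}

#' Write a greyscale image to PNG or TIFF
#'
#' @param img A [micro_image()].
#' @param path Output path ending in `.png` or `.tif`/`.tiff`.
#' @return `path`, invisibly.
#' @export
write_micro_image <- function(img, path) {
  stopifnot(inherits(img, "micro_image"))
  m <- img$pixels / 255
  m <- matrix(pmin(pmax(m, 0), 1), nrow(m), ncol(m))
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(m, target = path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(m, where = path, bits.per.sample = 8L)
  } else {
    abort("unsupported image format: use .png or .tif/.tiff")
  }
  invisible(path)
}

#' Read a greyscale image as a micro_image
#'
#' @param path PNG or TIFF file.
#' @param pixel_scale μm per pixel of the acquisition.
#' @param timepoint Acquisition time in minutes.
#' @return A [micro_image()]; multi-channel inputs are averaged to grey.
#' @export
read_micro_image <- function(path, pixel_scale = 7.2, timepoint = 0) {
  ext <- tolower(tools::file_ext(path))
  m <- if (ext == "png") png::readPNG(path) else if (ext %in% c("tif", "tiff")) {
    r <- tiff::readTIFF(path)
    if (is.list(r)) r[[1]] else r
  } else abort("unsupported image format: use .png or .tif/.tiff")
  if (length(dim(m)) == 3) m <- apply(m, c(1, 2), mean)
  micro_image(m * 255, pixel_scale = pixel_scale, timepoint = timepoint)
}
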