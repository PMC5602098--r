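#' Soil and straw reference colours of the scene renderer
#'
#' Mean 8-bit RGB colours used to paint soil and residue pixels. The four
#' soil types differ in brightness and hue, with vertisol (a dark,
#' moisture-retaining clay) the darkest. Straw is rendered with a strong
#' green excess relative to every soil, which is what the 2G-R-B
#' segmentation chain exploits.
#'
#' @return Named list: one RGB triplet per soil type plus `straw`.
#' @export
scene_palette <- function() {
  list(cambisol = c(160, 95, 95),
       leptosol = c(180, 120, 120),
       luvisol = c(150, 90, 100),
       vertisol = c(80, 45, 60),
       straw = c(185, 200, 50))
}

#' Generate a straw-on-soil field scene with exact ground truth
#'
#' Builds a boolean residue mask by rasterising random straw strokes
#' (line segments of configurable length and width, no anti-aliasing, so
#' every pixel is unambiguously residue or soil) until the counted cover
#' fraction is within `tol` percent points of `cover_target`; the last
#' stroke is trimmed pixel-by-pixel when it would overshoot. The mask is
#' then rendered to an 8-bit RGB image: straw and soil pixels take their
#' palette colours (interpolated by `contrast`), a common multiplicative
#' illumination factor per pixel, and a small independent per-channel
#' jitter.
#'
#' At `contrast = 1` the straw and soil colour distributions are disjoint
#' (in the excess-green index); at `contrast = 0` they are identical.
#'
#' @param cover_target Target percent cover in \[0, 100\].
#' @param soil Soil type, one of the [scene_palette()] soils.
#' @param width,height Image size in pixels.
#' @param pixel_size_cm Ground size of one pixel, cm.
#' @param contrast Straw/soil colour separation in \[0, 1\].
#' @param straw_length_cm,straw_width_cm Straw stroke dimensions, cm.
#' @param illumination Half-range of the per-pixel multiplicative
#'   illumination factor (uniform on `1 +/- illumination`).
#' @param jitter Half-range of the per-channel additive jitter, 8-bit
#'   counts.
#' @param tol Cover tolerance, percent points; must allow at least one
#'   pixel of slack.
#' @param seed Optional integer seed.
#' @return A list of class `"field_scene"`: `mask` (logical matrix, TRUE
#'   = residue), `image` (height x width x 3 integer array, 0-255),
#'   `true_cover` (percent, exact by pixel count), `pixel_size_cm`,
#'   `soil`, `contrast`, `extent_m2`.
#' @examples
#' sc <- generate_field_scene(50, width = 160, height = 120, seed = 1)
#' sc$true_cover
#' @export
generate_field_scene <- function(cover_target, soil = "cambisol",
                                 width = 1024L, height = 768L,
                                 pixel_size_cm = 0.27, contrast = 1,
                                 straw_length_cm = 30, straw_width_cm = 0.8,
                                 illumination = 0.10, jitter = 3,
                                 tol = 1, seed = NULL) {
  pal <- scene_palette()
  stopifnot(cover_target >= 0, cover_target <= 100,
            soil %in% setdiff(names(pal), "straw"),
            contrast >= 0, contrast <= 1, width >= 8, height >= 8)
  n_px <- as.numeric(width) * height
  if (tol <= 0 || tol / 100 * n_px < 1) {
    stop("tol is impossible at this resolution: it allows less than one pixel of slack")
  }
  if (!is.null(seed)) set.seed(seed)

  mask <- matrix(FALSE, height, width)
  want <- cover_target / 100 * n_px
  slack <- tol / 100 * n_px
  if (cover_target >= 100) {
    mask[] <- TRUE
  } else if (cover_target > 0) {
    len_px <- max(2, straw_length_cm / pixel_size_cm)
    wid_px <- max(1, straw_width_cm / pixel_size_cm)
    offs <- expand.grid(t = seq(0, len_px, by = 0.6),
                        u = seq(-wid_px / 2, wid_px / 2, by = 0.6))
    count <- 0
    while (count < want - slack) {
      x0 <- stats::runif(1, 1, width); y0 <- stats::runif(1, 1, height)
      th <- stats::runif(1, 0, pi)
      xs <- round(x0 + offs$t * cos(th) - offs$u * sin(th))
      ys <- round(y0 + offs$t * sin(th) + offs$u * cos(th))
      ok <- xs >= 1 & xs <= width & ys >= 1 & ys <= height
      cells <- unique((xs[ok] - 1) * height + ys[ok])
      new <- cells[!mask[cells]]
      over <- (count + length(new)) - (want + slack)
      if (over > 0) {        # trim the final stroke to stay within tolerance
        new <- sample(new, max(0, length(new) - ceiling(over)))
      }
      mask[new] <- TRUE
      count <- count + length(new)
    }
  }
  true_cover <- 100 * sum(mask) / n_px

  soil_rgb <- pal[[soil]]
  straw_rgb <- soil_rgb + contrast * (pal$straw - soil_rgb)
  img <- array(0L, c(height, width, 3L))
  f <- matrix(stats::runif(n_px, 1 - illumination, 1 + illumination),
              height, width)
  for (k in 1:3) {
    base <- ifelse(mask, straw_rgb[k], soil_rgb[k])
    img[, , k] <- as.integer(pmin(255, pmax(0, round(
      base * f + stats::runif(n_px, -jitter, jitter)))))
  }
  structure(list(mask = mask, image = img, true_cover = true_cover,
                 pixel_size_cm = pixel_size_cm, soil = soil,
                 contrast = contrast,
                 extent_m2 = n_px * (pixel_size_cm / 100)^2),
            class = "field_scene")
}

#' @export
print.field_scene <- function(x, ...) {
  cat(sprintf("Field scene %dx%d px (%.2f cm/px, %.1f m2), soil %s\n",
              ncol(x$mask), nrow(x$mask), x$pixel_size_cm, x$extent_m2,
              x$soil))
  cat(sprintf("  true cover %.2f%%, contrast %.2f\n", x$true_cover,
              x$contrast))
  invisible(x)
}

#' Render a two-band shortwave-infrared raster over surveyed plots
#'
#' Emulates a 30 m resolution two-band (SWIR1/SWIR2) reflectance scene in
#' which residue cover depresses SWIR2 relative to SWIR1 (the cellulose
#' absorption signal the tillage index exploits):
#' `swir2 = swir1 * (1 - k * cover/100) * (1 + eps)` with multiplicative
#' noise `eps ~ N(0, noise_sd)`; pixels on vertisol receive extra
#' perturbation `N(0, vertisol_sd)` emulating the spectral effect of
#' dark, moist clay. The pixel containing each plot point takes that
#' plot's cover; background pixels have zero cover. With `noise_sd = 0`
#' and `vertisol_sd = 0` the pixel tillage index is strictly increasing
#' in cover.
#'
#' @param plots data.frame with columns `x`, `y` (map coordinates, m),
#'   `cover` (percent) and optionally `soil`.
#' @param nrow_px,ncol_px Raster dimensions in 30 m pixels; defaults
#'   cover the plot extent.
#' @param origin Map coordinates of the top-left corner of the top-left
#'   pixel; default places all plots inside.
#' @param pixel_size Pixel size, m.
#' @param base_reflectance Mean SWIR1 reflectance of bare soil.
#' @param k Cover attenuation coefficient of SWIR2, `> 0`.
#' @param noise_sd,vertisol_sd Multiplicative noise levels.
#' @param seed Optional integer seed.
#' @return A list of class `"spectral_scene"`: `swir1`, `swir2`
#'   (matrices in \[0, 1\]), `geotransform` (list `origin_x`, `origin_y`,
#'   `pixel_size`), `plots` (the input with pixel indices attached).
#' @export
render_spectral_scene <- function(plots, nrow_px = NULL, ncol_px = NULL,
                                  origin = NULL, pixel_size = 30,
                                  base_reflectance = 0.30, k = 0.4,
                                  noise_sd = 0.15, vertisol_sd = 0.06,
                                  seed = NULL) {
  stopifnot(is.data.frame(plots), all(c("x", "y", "cover") %in% names(plots)),
            all(plots$cover >= 0 & plots$cover <= 100), k > 0,
            noise_sd >= 0, vertisol_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(origin)) {
    origin <- c(min(plots$x) - pixel_size, max(plots$y) + pixel_size)
  }
  if (is.null(ncol_px)) {
    ncol_px <- ceiling((max(plots$x) - origin[1]) / pixel_size) + 1L
  }
  if (is.null(nrow_px)) {
    nrow_px <- ceiling((origin[2] - min(plots$y)) / pixel_size) + 1L
  }
  col <- floor((plots$x - origin[1]) / pixel_size) + 1L
  row <- floor((origin[2] - plots$y) / pixel_size) + 1L
  if (any(col < 1 | col > ncol_px | row < 1 | row > nrow_px)) {
    stop("plot coordinate outside the raster extent")
  }
  n_px <- nrow_px * ncol_px
  cover <- matrix(0, nrow_px, ncol_px)
  vert <- matrix(FALSE, nrow_px, ncol_px)
  cell <- (col - 1L) * nrow_px + row
  cover[cell] <- plots$cover
  if (!is.null(plots$soil)) vert[cell] <- plots$soil == "vertisol"

  swir1 <- base_reflectance * matrix(stats::rnorm(n_px, 1, 0.05),
                                     nrow_px, ncol_px)
  eps <- stats::rnorm(n_px, 0, noise_sd) +
    stats::rnorm(n_px, 0, vertisol_sd) * vert
  swir2 <- swir1 * (1 - k * cover / 100) * (1 + matrix(eps, nrow_px, ncol_px))
  clamp01 <- function(m) pmin(pmax(m, 0), 1)  # m first: keeps dim attributes
  plots$pixel_row <- row; plots$pixel_col <- col
  structure(list(swir1 = clamp01(swir1), swir2 = clamp01(swir2),
                 geotransform = list(origin_x = origin[1],
                                     origin_y = origin[2],
                                     pixel_size = pixel_size),
                 plots = plots),
            class = "spectral_scene")
}

#' @export
print.spectral_scene <- function(x, ...) {
  cat(sprintf("Spectral scene %dx%d px at %g m, origin (%g, %g); %d plots\n",
              ncol(x$swir1), nrow(x$swir1), x$geotransform$pixel_size,
              x$geotransform$origin_x, x$geotransform$origin_y,
              nrow(x$plots)))
  invisible(x)
}

#' Field-scene PNG input/output
#'
#' `write_field_scene()` writes the rendered RGB image and, alongside it,
#' the ground-truth mask as a single-channel PNG (white = residue). Both
#' round-trip losslessly at 8 bits. `read_field_image()` reads any RGB
#' PNG back as a 0-255 integer array; `read_field_mask()` reads a mask
#' PNG back as a logical matrix.
#'
#' @param scene A `"field_scene"`.
#' @param image_path,mask_path Output PNG paths (mask omitted if
#'   `mask_path` is `NULL`).
#' @return `write_field_scene()` invisibly returns the paths written.
#' @export
write_field_scene <- function(scene, image_path, mask_path = NULL) {
  stopifnot(inherits(scene, "field_scene"))
  png::writePNG(scene$image / 255, image_path)
  if (!is.null(mask_path)) png::writePNG(scene$mask * 1, mask_path)
  invisible(c(image = image_path, mask = mask_path))
}

#' @rdname write_field_scene
#' @param path PNG path to read.
#' @export
read_field_image <- function(path) {
  arr <- png::readPNG(path)
  if (length(dim(arr)) != 3L || dim(arr)[3] < 3L) {
    stop("expected an RGB PNG")
  }
  array(as.integer(round(arr[, , 1:3] * 255)), dim = c(dim(arr)[1:2], 3L))
}

#' @rdname write_field_scene
#' @export
read_field_mask <- function(path) {
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 3L) arr <- arr[, , 1L]
  arr > 0.5
}

#' Two-band raster input/output with a world-file geotransform
#'
#' Writes the SWIR1/SWIR2 bands as a two-directory 32-bit float TIFF and
#' the affine geotransform as an ESRI world file (same path with a
#' `.tfw` extension): six plain-text lines holding the pixel size, the
#' (zero) rotation terms and the map coordinates of the centre of the
#' top-left pixel. `read_spectral_scene()` reverses both.
#'
#' @param scene A `"spectral_scene"`.
#' @param path Output `.tif` path.
#' @return `write_spectral_scene()` invisibly returns the paths written;
#'   `read_spectral_scene()` returns a `"spectral_scene"` (without plot
#'   points).
#' @export
write_spectral_scene <- function(scene, path) {
  stopifnot(inherits(scene, "spectral_scene"))
  tiff::writeTIFF(list(scene$swir1, scene$swir2), path,
                  bits.per.sample = 32L)
  gt <- scene$geotransform
  wf <- sub("\\.tiff?$", "", path, ignore.case = TRUE)
  wf <- paste0(wf, ".tfw")
  writeLines(format(c(gt$pixel_size, 0, 0, -gt$pixel_size,
                      gt$origin_x + gt$pixel_size / 2,
                      gt$origin_y - gt$pixel_size / 2),
                    nsmall = 6, trim = TRUE, scientific = FALSE), wf)
  invisible(c(tif = path, tfw = wf))
}

#' @rdname write_spectral_scene
#' @export
read_spectral_scene <- function(path) {
  bands <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e) stop("malformed TIFF: ",
                                             conditionMessage(e)))
  if (length(bands) != 2L) stop("expected a two-band raster")
  wf <- paste0(sub("\\.tiff?$", "", path, ignore.case = TRUE), ".tfw")
  if (!file.exists(wf)) stop("missing world file: ", wf)
  w <- as.numeric(readLines(wf))
  if (length(w) != 6L || any(!is.finite(w))) stop("malformed world file: ", wf)
  structure(list(swir1 = bands[[1]], swir2 = bands[[2]],
                 geotransform = list(origin_x = w[5] - w[1] / 2,
                                     origin_y = w[6] + w[1] / 2,
                                     pixel_size = w[1]),
                 plots = NULL),
            class = "spectral_scene")
}
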