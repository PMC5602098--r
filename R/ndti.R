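#' Normalized Difference Tillage Index from SWIR bands
#'
#' Computes per pixel `(swir1 - swir2) / (swir1 + swir2)`, the standard
#' normalized-difference form of the tillage index: residue's cellulose
#' absorption depresses SWIR2 relative to SWIR1, so higher values signal
#' more residue. Pixels where both bands are zero have no defined index
#' and are flagged invalid (`NA`).
#'
#' @param swir1,swir2 Reflectance matrices of the same shape, values
#'   `>= 0`, or a `"spectral_scene"` as the first argument.
#' @return A matrix of class `"ndti_grid"` with values in \[-1, 1\] and
#'   attribute `scaled = FALSE`.
#' @examples
#' compute_ndti(matrix(0.3), matrix(0.1))  # 0.5
#' @export
compute_ndti <- function(swir1, swir2 = NULL) {
  if (inherits(swir1, "spectral_scene")) {
    swir2 <- swir1$swir2; swir1 <- swir1$swir1
  }
  stopifnot(is.matrix(swir1), is.matrix(swir2))
  if (!all(dim(swir1) == dim(swir2))) stop("band shape mismatch")
  if (any(swir1 < 0, na.rm = TRUE) || any(swir2 < 0, na.rm = TRUE)) {
    stop("negative reflectance")
  }
  denom <- swir1 + swir2
  vals <- ifelse(denom > 0, (swir1 - swir2) / denom, NA_real_)
  structure(matrix(vals, nrow(swir1), ncol(swir1)),
            scaled = FALSE, class = "ndti_grid")
}

#' Scale a raw tillage index grid to 0-100
#'
#' Applies the fixed affine map `(raw + 1) * 50` so the index becomes
#' comparable with percent-cover measurements. No empirical calibration
#' is applied. Invalid pixels stay invalid; an already-scaled grid is
#' rejected.
#'
#' @param raw An `"ndti_grid"` with `scaled = FALSE`.
#' @return An `"ndti_grid"` in \[0, 100\] with `scaled = TRUE`.
#' @export
scale_ndti <- function(raw) {
  stopifnot(inherits(raw, "ndti_grid"))
  if (isTRUE(attr(raw, "scaled"))) stop("grid is already scaled")
  structure(matrix((unclass(raw) + 1) * 50, nrow(raw), ncol(raw)),
            scaled = TRUE, class = "ndti_grid")
}

#' @export
print.ndti_grid <- function(x, ...) {
  cat(sprintf("NDTI grid %dx%d (%s), range [%.3g, %.3g], %d invalid px\n",
              ncol(x), nrow(x),
              if (isTRUE(attr(x, "scaled"))) "scaled 0-100" else "raw",
              min(x, na.rm = TRUE), max(x, na.rm = TRUE), sum(is.na(x))))
  invisible(x)
}

#' Extract per-plot values from a scaled tillage-index raster
#'
#' Each plot takes the value of the single 30 m pixel containing its
#' point (default), or the mean of the 3x3 pixel block centred there
#' (`mode = "mean3"`; edge plots average the available pixels). Points
#' exactly on a pixel boundary belong to the pixel to their lower-right
#' (half-open pixel convention). Invalid pixels propagate as `NA`.
#'
#' @param grid A scaled `"ndti_grid"`.
#' @param geotransform List with `origin_x`, `origin_y` (map coordinates
#'   of the top-left corner of the top-left pixel) and `pixel_size`.
#' @param points data.frame with columns `x` and `y` in map coordinates.
#' @param mode `"pixel"` or `"mean3"`.
#' @return Numeric vector, one value per point.
#' @export
extract_plot_value <- function(grid, geotransform, points,
                               mode = c("pixel", "mean3")) {
  mode <- match.arg(mode)
  stopifnot(inherits(grid, "ndti_grid"), isTRUE(attr(grid, "scaled")),
            is.data.frame(points), all(c("x", "y") %in% names(points)))
  gt <- geotransform
  px <- gt$pixel_size
  col <- floor((points$x - gt$origin_x) / px) + 1L
  row <- floor((gt$origin_y - points$y) / px) + 1L
  if (any(col < 1 | col > ncol(grid) | row < 1 | row > nrow(grid))) {
    stop("point outside the raster extent")
  }
  m <- unclass(grid)
  if (mode == "pixel") {
    return(m[(col - 1L) * nrow(m) + row])
  }
  vapply(seq_along(col), function(i) {
    rr <- max(1L, row[i] - 1L):min(nrow(m), row[i] + 1L)
    cc <- max(1L, col[i] - 1L):min(ncol(m), col[i] + 1L)
    mean(m[rr, cc])
  }, numeric(1))
}
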