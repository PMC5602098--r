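#' Per-channel colour balance by saturation stretch
#'
#' Linearly stretches each channel so that its lowest and highest
#' `floor(n * saturation_fraction / 2)` pixels saturate at 0 and 255 and
#' the remaining range maps affinely onto \[0, 255\], enhancing contrast
#' before index computation. The default saturation matches the common
#' contrast-enhancement default of desktop image-analysis tools (0.35%
#' per tail). A constant channel (after clipping) has no defined stretch
#' and is returned unchanged with a warning.
#'
#' @param image Height x width x 3 integer array of 8-bit RGB values.
#' @param saturation_fraction Total fraction of pixels clipped, in
#'   \[0, 1).
#' @return Integer array of the same shape, values in 0-255.
#' @export
color_balance <- function(image, saturation_fraction = 0.007) {
  check_rgb(image)
  stopifnot(saturation_fraction >= 0, saturation_fraction < 1)
  out <- image
  n <- prod(dim(image)[1:2])
  n_clip <- floor(n * saturation_fraction / 2)  # pixels saturated per tail
  for (k in 1:3) {
    ch <- image[, , k]
    s <- sort(ch)
    q <- c(s[n_clip + 1L], s[n - n_clip])
    if (q[1] == q[2]) {
      warning(sprintf("channel %d is constant after clipping; returned unchanged", k))
      next
    }
    out[, , k] <- as.integer(pmin(255, pmax(0, round(
      (ch - q[1]) * 255 / (q[2] - q[1])))))
  }
  out
}

#' Excess-green index 2G - R - B
#'
#' Computes, per pixel, twice the green channel minus the red and blue
#' channels in signed arithmetic, so values range over \[-510, 510\] for
#' 8-bit input. Residue (straw) pixels score high, soil pixels low.
#'
#' @param image Height x width x 3 array of 8-bit RGB values.
#' @return Signed integer matrix of the same height and width.
#' @examples
#' px <- array(c(210, 190, 120), c(1, 1, 3))
#' excess_index(px)  # 2*190 - 210 - 120 = 50
#' @export
excess_index <- function(image) {
  check_rgb(image)
  r <- as.numeric(image[, , 1]); g <- as.numeric(image[, , 2])
  b <- as.numeric(image[, , 3])
  matrix(as.integer(2 * g - r - b), dim(image)[1], dim(image)[2])
}

check_rgb <- function(image) {
  if (length(dim(image)) != 3L || dim(image)[3] != 3L) {
    stop("expected a height x width x 3 RGB array")
  }
  invisible(TRUE)
}

#' Otsu's threshold of an integer-valued grid
#'
#' Exhaustive histogram search for the cut maximising the between-class
#' variance. Deterministic; errors on an all-equal grid (no split
#' exists). Returned with attribute `eta`, the ratio of between-class to
#' total variance at the optimum.
#'
#' @param values Integer vector or matrix.
#' @return The threshold level `t` such that `values > t` is the
#'   high (residue) class.
#' @export
otsu_threshold <- function(values) {
  v <- as.integer(values)
  v <- v[!is.na(v)]
  if (length(v) == 0L) stop("empty grid")
  rng <- range(v)
  if (rng[1] == rng[2]) {
    stop("all grid values are equal; Otsu is undefined - use a fixed threshold")
  }
  counts <- as.numeric(tabulate(v - rng[1] + 1L, rng[2] - rng[1] + 1L))
  levels <- seq(rng[1], rng[2])
  n <- length(v)
  w1 <- cumsum(counts)
  s1 <- cumsum(counts * levels)
  s_tot <- s1[length(s1)]
  between <- (s_tot * w1 - s1 * n)^2 / (w1 * (n - w1)) / n^2
  between[!is.finite(between)] <- -Inf
  k <- which.max(between)
  sig_tot <- sum(counts * levels^2) / n - (s_tot / n)^2
  structure(levels[k], eta = between[k] / sig_tot)
}

#' Binarise an index grid into a residue mask
#'
#' Pixels strictly above the threshold become residue (`TRUE`, the
#' "white" class); ties fall to soil. With `method = "otsu"` the
#' threshold is the deterministic Otsu optimum of the grid; with
#' `method = "fixed"` it is `threshold`.
#'
#' @param index Signed integer matrix, e.g. from [excess_index()].
#' @param method `"otsu"` (default) or `"fixed"`.
#' @param threshold Numeric cut, required for `method = "fixed"`.
#' @return Logical matrix of the same shape, `TRUE` = residue.
#' @export
binarize <- function(index, method = c("otsu", "fixed"), threshold = NULL) {
  method <- match.arg(method)
  stopifnot(is.matrix(index))
  th <- if (method == "otsu") {
    otsu_threshold(index)
  } else {
    if (is.null(threshold)) stop("method 'fixed' requires a threshold")
    threshold
  }
  index > as.numeric(th)
}

#' Cover fraction of a binary residue mask
#'
#' @param mask Logical matrix, `TRUE` = residue.
#' @return Percent of residue pixels, in \[0, 100\].
#' @export
cover_fraction <- function(mask) {
  stopifnot(is.matrix(mask), is.logical(mask))
  if (length(mask) == 0L) stop("empty mask")
  100 * sum(mask) / length(mask)
}

#' Estimate residue cover from an RGB field image
#'
#' The full image-processing chain: per-channel colour balance, the
#' excess-green (2G - R - B) index, binarisation, and the residue pixel
#' fraction. Before thresholding, a homogeneity guard checks the spread
#' of the raw index: when its standard deviation falls below
#' `homogeneity_sd` the image has no two-class structure (all soil or all
#' straw) and Otsu would split noise, so the scene is classified
#' wholesale by the sign of its mean excess-green index. The guard is
#' bypassed for a fixed threshold.
#'
#' @param image Height x width x 3 array of 8-bit RGB values.
#' @param method,threshold Passed to [binarize()].
#' @param saturation_fraction Passed to [color_balance()].
#' @param homogeneity_sd Raw-index standard deviation below which the
#'   scene is declared homogeneous (Otsu only). Set to 0 to disable.
#' @param keep_intermediates If `TRUE`, the balanced image, index grid
#'   and mask are attached as attributes.
#' @return Estimated percent cover.
#' @examples
#' sc <- generate_field_scene(40, width = 160, height = 120, seed = 2)
#' segment_cover(sc$image)
#' @export
segment_cover <- function(image, method = c("otsu", "fixed"),
                          threshold = NULL, saturation_fraction = 0.007,
                          homogeneity_sd = 15,
                          keep_intermediates = FALSE) {
  method <- match.arg(method)
  check_rgb(image)
  raw <- excess_index(image)
  if (method == "otsu" && homogeneity_sd > 0 &&
      stats::sd(raw) < homogeneity_sd) {
    return(if (mean(raw) > 0) 100 else 0)
  }
  balanced <- color_balance(image, saturation_fraction)
  index <- excess_index(balanced)
  mask <- binarize(index, method, threshold)
  est <- cover_fraction(mask)
  if (keep_intermediates) {
    attr(est, "balanced") <- balanced
    attr(est, "index") <- index
    attr(est, "mask") <- mask
  }
  est
}
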