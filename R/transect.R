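#' Read one line transect over a ground-truth residue mask
#'
#' Simulates laying a marked rope across the field and looking straight
#' down at each mark: the reading is the number of marks whose containing
#' grid cell is residue. Marks sit at the midpoints of `n_marks` equal
#' intervals along the segment (a 30 m rope marked at 1 m intervals reads
#' at 0.5 m, 1.5 m, ...), and a mark intersects residue iff its cell is
#' residue - point sampling, no mark width.
#'
#' @param mask Logical matrix, `TRUE` = residue; row 1 is the top edge.
#' @param start,end Segment endpoints in metres, `c(x, y)` with the
#'   origin at the top-left field corner, x rightward along columns and y
#'   downward along rows.
#' @param n_marks Number of marks on the rope.
#' @param pixel_size_m Ground size of one cell, metres.
#' @return A list of class `"transect_reading"`: `start`, `end`, `marks`
#'   (n_marks x 2 matrix of metre positions), `hits` (count in
#'   \[0, n_marks\]).
#' @export
read_transect <- function(mask, start, end, n_marks = 30L,
                          pixel_size_m) {
  stopifnot(is.matrix(mask), is.logical(mask), length(start) == 2L,
            length(end) == 2L, n_marks >= 1L, pixel_size_m > 0)
  w_m <- ncol(mask) * pixel_size_m
  h_m <- nrow(mask) * pixel_size_m
  pts <- rbind(start, end)
  if (any(pts[, 1] < 0 | pts[, 1] > w_m | pts[, 2] < 0 | pts[, 2] > h_m)) {
    stop("transect line exits the field extent")
  }
  tt <- (seq_len(n_marks) - 0.5) / n_marks
  mx <- start[1] + tt * (end[1] - start[1])
  my <- start[2] + tt * (end[2] - start[2])
  col <- pmin(ncol(mask), floor(mx / pixel_size_m) + 1L)
  row <- pmin(nrow(mask), floor(my / pixel_size_m) + 1L)
  hits <- sum(mask[(col - 1L) * nrow(mask) + row])
  structure(list(start = start, end = end,
                 marks = cbind(x = mx, y = my), hits = as.integer(hits),
                 n_marks = as.integer(n_marks)),
            class = "transect_reading")
}

#' @export
print.transect_reading <- function(x, ...) {
  cat(sprintf("Transect (%.1f,%.1f)-(%.1f,%.1f): %d/%d marks over residue\n",
              x$start[1], x$start[2], x$end[1], x$end[2], x$hits, x$n_marks))
  invisible(x)
}

#' Line-transect estimate of field residue cover
#'
#' The benchmark protocol: at each of the four field corners a rope is
#' laid along the corner's inward diagonal bisector, the marks over
#' residue are counted, and the four per-transect percentages
#' (hits / n_marks x 100) are averaged. If the rope is longer than the
#' field diagonal the transect is clipped to the diagonal with a warning
#' and the marks rescale to the clipped length. With a seed, the start of
#' each transect is jittered up to 0.5 m inward along its diagonal
#' (enumerator placement variation).
#'
#' Estimates are multiples of `100 / (4 * n_marks)`.
#'
#' @param scene A `"field_scene"`, or a logical mask (then
#'   `pixel_size_m` is required).
#' @param pixel_size_m Cell size in metres (taken from the scene if
#'   omitted).
#' @param rope_m Rope length, metres.
#' @param n_marks Marks per rope.
#' @param seed Optional integer seed for placement jitter; `NULL` places
#'   each rope exactly at its corner.
#' @return Estimated percent cover, with attribute `readings` (list of
#'   four [read_transect()] results).
#' @examples
#' sc <- generate_field_scene(50, width = 160, height = 120, seed = 3)
#' suppressWarnings(lt_estimate(sc))
#' @export
lt_estimate <- function(scene, pixel_size_m = NULL, rope_m = 30,
                        n_marks = 30L, seed = NULL) {
  if (inherits(scene, "field_scene")) {
    mask <- scene$mask
    if (is.null(pixel_size_m)) pixel_size_m <- scene$pixel_size_cm / 100
  } else {
    mask <- scene
    if (is.null(pixel_size_m)) stop("pixel_size_m is required with a bare mask")
  }
  stopifnot(is.matrix(mask), is.logical(mask), pixel_size_m > 0)
  if (!is.null(seed)) set.seed(seed)
  w <- ncol(mask) * pixel_size_m
  h <- nrow(mask) * pixel_size_m
  # the 45-degree bisector from a corner exits at the shorter side
  len_max <- sqrt(2) * min(w, h)
  len <- rope_m
  if (len > len_max) {
    warning(sprintf(paste0("field too small for the rope (%g m > %.2f m ",
                           "along the corner diagonal); transect clipped, ",
                           "marks rescaled"),
                    rope_m, len_max))
    len <- len_max
  }
  corners <- list(c(0, 0), c(w, 0), c(0, h), c(w, h))
  dirs <- list(c(1, 1), c(-1, 1), c(1, -1), c(-1, -1))
  readings <- vector("list", 4L)
  for (i in 1:4) {
    u <- dirs[[i]] / sqrt(2)
    off <- if (!is.null(seed)) stats::runif(1, 0, max(0, min(0.5, len_max - len))) else 0
    s <- corners[[i]] + u * off
    e <- s + u * len
    e <- pmin(pmax(e, 0), c(w, h))  # numeric safety at the far corner
    readings[[i]] <- read_transect(mask, s, e, n_marks, pixel_size_m)
  }
  hits <- vapply(readings, function(r) r$hits, integer(1))
  structure(mean(hits / n_marks) * 100, readings = readings)
}
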