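as_rgb <- function(r, g, b) {
  stopifnot(length(r) == length(g), length(g) == length(b))
  array(as.integer(c(r, g, b)), c(length(r), 1L, 3L))
}

test_that("colour balance stretches each channel between its clip quantiles", {
  # a channel already spanning [0, 255] is unchanged at zero saturation
  full <- as_rgb(c(0, 255, 17), c(0, 255, 100), c(0, 255, 200))
  expect_identical(color_balance(full, 0), full)
  # values {50..150} map affinely onto [0, 255]
  ch <- seq(50, 150, by = 10)
  img <- as_rgb(ch, ch, ch)
  out <- color_balance(img, 0)
  expect_identical(out[1, 1, 1], 0L)
  expect_identical(out[11, 1, 1], 255L)
  expect_identical(out[, 1, 1], as.integer(round((ch - 50) * 255 / 100)))
  # 100 pixels at 2% saturation: exactly the lowest and highest pixel clip
  ch <- as.integer(seq(10, 109))
  out <- color_balance(as_rgb(ch, ch, ch), 0.02)
  expect_identical(out[1, 1, 1], 0L)    # clipped low
  expect_identical(out[2, 1, 1], 0L)    # new minimum after clipping
  expect_identical(out[100, 1, 1], 255L)
  expect_identical(out[99, 1, 1], 255L)
  expect_identical(sum(out[, 1, 1] == 0L), 2L)
  expect_identical(sum(out[, 1, 1] == 255L), 2L)
})

test_that("constant channels survive colour balance with a warning", {
  img <- as_rgb(rep(100L, 5), 1:5 * 10L, 2:6 * 7L)
  expect_warning(out <- color_balance(img, 0), "channel 1 is constant")
  expect_identical(out[, 1, 1], rep(100L, 5))
  expect_false(all(out[, 1, 2] == img[, 1, 2]))
})

test_that("the excess-green index is 2G - R - B in signed arithmetic", {
  expect_identical(excess_index(as_rgb(128L, 128L, 128L))[1, 1], 0L)
  expect_identical(excess_index(as_rgb(0L, 255L, 0L))[1, 1], 510L)
  expect_identical(excess_index(as_rgb(255L, 0L, 255L))[1, 1], -510L)
  expect_identical(excess_index(as_rgb(210L, 190L, 120L))[1, 1], 50L)
  expect_error(excess_index(matrix(1, 2, 2)), "RGB")
})

test_that("binarisation follows the strict threshold convention", {
  # perfectly bimodal grid: Otsu separates the modes
  grid <- matrix(c(rep(-100L, 60), rep(100L, 40)), 10, 10)
  expect_identical(sum(binarize(grid)), 40L)
  # fixed threshold is strict: ties fall to soil
  expect_identical(binarize(matrix(c(-1L, 0L, 1L), 1), "fixed", 0)[1, ],
                   c(FALSE, FALSE, TRUE))
  expect_error(binarize(matrix(5L, 3, 3)), "fixed threshold")
  expect_error(binarize(matrix(1:4, 2), "fixed"), "requires a threshold")
})

test_that("Otsu matches an exhaustive within-class-variance search", {
  set.seed(42)
  # two-Gaussian mixture: threshold lands between the modes
  v <- as.integer(round(c(rnorm(5000, -50, 10), rnorm(5000, 50, 10))))
  th <- otsu_threshold(v)
  expect_gt(th, -20); expect_lt(th, 20)
  expect_equal(otsu_objective(v, th), otsu_objective(v, otsu_brute_force(v)),
               tolerance = 1e-12)
  # random small grids: the histogram implementation equals brute force
  for (i in 1:20) {
    v <- as.integer(sample(-30:30, 60, TRUE))
    if (length(unique(v)) < 2) next
    expect_equal(otsu_objective(v, otsu_threshold(v)),
                 otsu_objective(v, otsu_brute_force(v)), tolerance = 1e-12)
  }
  expect_error(otsu_threshold(matrix(3L, 2, 2)), "fixed threshold")
})

test_that("cover fraction counts residue pixels", {
  m <- matrix(FALSE, 10, 10); m[1:25] <- TRUE
  expect_identical(cover_fraction(m), 25)
  expect_identical(cover_fraction(matrix(FALSE, 5, 5)), 0)
  expect_identical(cover_fraction(matrix(TRUE, 5, 5)), 100)
  expect_error(cover_fraction(matrix(logical(0), 0, 0)), "empty")
})

test_that("the segmentation chain recovers cover on high-contrast scenes", {
  for (s in 1:8) {
    tgt <- c(10, 25, 40, 55, 70, 85, 30, 60)[s]
    soil <- c("cambisol", "leptosol", "luvisol", "vertisol")[(s %% 4) + 1]
    sc <- generate_field_scene(tgt, soil = soil, width = 240, height = 180,
                               seed = 50 + s)
    expect_lt(abs(segment_cover(sc$image) - sc$true_cover), 5)
  }
})

test_that("segmentation is deterministic and scale-equivariant", {
  sc <- generate_field_scene(45, width = 160, height = 120, seed = 9)
  e1 <- segment_cover(sc$image)
  expect_identical(segment_cover(sc$image), e1)
  # nearest-neighbour 2x upsampling duplicates every pixel equally
  up <- sc$image[rep(seq_len(120), each = 2), rep(seq_len(160), each = 2), ]
  expect_identical(segment_cover(up), e1)
})

test_that("homogeneous scenes fall back to wholesale classification", {
  soil_only <- generate_field_scene(0, width = 160, height = 120, seed = 12)
  expect_lt(segment_cover(soil_only$image), 5)
  straw_only <- generate_field_scene(100, width = 160, height = 120, seed = 12)
  expect_gt(segment_cover(straw_only$image), 95)
})

test_that("segmentation error grows as colour contrast degrades", {
  mae <- vapply(c(1, 0.6, 0.3, 0.08), function(ct) {
    errs <- vapply(1:6, function(s) {
      sc <- generate_field_scene(c(20, 35, 50, 65, 80, 45)[s], contrast = ct,
                                 soil = c("cambisol", "vertisol", "luvisol",
                                          "leptosol", "cambisol", "vertisol")[s],
                                 width = 240, height = 180, seed = 70 + s)
      abs(segment_cover(sc$image) - sc$true_cover)
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  expect_true(all(diff(mae) >= 0))
})
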