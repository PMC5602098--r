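test_that("field scenes hit the cover target with exact ground truth", {
  sc0 <- generate_field_scene(0, width = 120, height = 90, seed = 1)
  expect_identical(sum(sc0$mask), 0L)
  expect_identical(sc0$true_cover, 0)
  sc100 <- generate_field_scene(100, width = 120, height = 90, seed = 1)
  expect_true(all(sc100$mask))
  expect_identical(sc100$true_cover, 100)
  for (tgt in c(15, 50, 85)) {
    sc <- generate_field_scene(tgt, width = 240, height = 180, seed = tgt)
    expect_lte(abs(sc$true_cover - tgt), 1)
    # cover is counted, not estimated
    expect_identical(sc$true_cover, 100 * sum(sc$mask) / length(sc$mask))
    expect_identical(dim(sc$image)[1:2], dim(sc$mask))
  }
})

test_that("impossible cover tolerance is signalled", {
  expect_error(generate_field_scene(50, width = 100, height = 100, tol = 0),
               "impossible")
  expect_error(generate_field_scene(50, width = 20, height = 20,
                                    tol = 0.01),
               "impossible")
})

test_that("contrast controls straw/soil colour separability", {
  sc1 <- generate_field_scene(50, width = 240, height = 180, contrast = 1,
                              seed = 5)
  idx1 <- excess_index(sc1$image)
  expect_gt(min(idx1[sc1$mask]), max(idx1[!sc1$mask]))  # disjoint at 1
  sc0 <- generate_field_scene(50, width = 240, height = 180, contrast = 0,
                              seed = 5)
  idx0 <- excess_index(sc0$image)
  # identical colour distributions at 0: class means indistinguishable
  expect_lt(abs(mean(idx0[sc0$mask]) - mean(idx0[!sc0$mask])), 1)
  # intermediate contrast shrinks the gap monotonically
  gap <- function(ct) {
    sc <- generate_field_scene(50, width = 240, height = 180, contrast = ct,
                               seed = 5)
    idx <- excess_index(sc$image)
    mean(idx[sc$mask]) - mean(idx[!sc$mask])
  }
  gaps <- vapply(c(1, 0.6, 0.3, 0), gap, numeric(1))
  expect_true(all(diff(gaps) < 0))
})

test_that("scene PNG output round-trips losslessly", {
  sc <- generate_field_scene(35, width = 80, height = 60, seed = 2)
  img_path <- withr::local_tempfile(fileext = ".png")
  mask_path <- withr::local_tempfile(fileext = ".png")
  write_field_scene(sc, img_path, mask_path)
  expect_identical(read_field_image(img_path), sc$image)
  expect_identical(read_field_mask(mask_path), sc$mask)
  # truncated files fail loudly
  bad <- withr::local_tempfile(fileext = ".png")
  writeBin(readBin(img_path, "raw", 40), bad)
  expect_error(read_field_image(bad))
})

test_that("spectral rasters round-trip values and geotransform", {
  pts <- data.frame(x = c(100, 400, 800), y = c(900, 500, 120),
                    cover = c(0, 50, 100),
                    soil = c("cambisol", "vertisol", "luvisol"))
  sc <- render_spectral_scene(pts, seed = 7)
  tif <- withr::local_tempfile(fileext = ".tif")
  write_spectral_scene(sc, tif)
  back <- read_spectral_scene(tif)
  expect_equal(back$swir1, sc$swir1, tolerance = 1e-6)  # 32-bit storage
  expect_equal(back$swir2, sc$swir2, tolerance = 1e-6)
  expect_equal(back$geotransform, sc$geotransform)
  expect_identical(back$geotransform$pixel_size, 30)
  # malformed input
  bad <- withr::local_tempfile(fileext = ".tif")
  writeBin(as.raw(1:32), bad)
  expect_error(read_spectral_scene(bad), "malformed")
  file.remove(paste0(sub("\\.tif$", "", tif), ".tfw"))
  expect_error(read_spectral_scene(tif), "world file")
})

test_that("noise-free SWIR signal makes the tillage index increase with cover", {
  pts <- data.frame(x = c(50, 350, 650), y = c(650, 350, 50),
                    cover = c(0, 50, 100))
  sc <- render_spectral_scene(pts, noise_sd = 0, vertisol_sd = 0, k = 0.4,
                              seed = 1)
  nd <- scale_ndti(compute_ndti(sc))
  v <- extract_plot_value(nd, sc$geotransform, pts)
  expect_identical(order(v), 1:3)
  expect_equal(v[1], 50)  # zero cover: both bands equal, raw index 0
  # reflectances stay physical
  expect_true(all(sc$swir1 >= 0 & sc$swir1 <= 1))
  expect_true(all(sc$swir2 >= 0 & sc$swir2 <= 1))
})

test_that("plot coordinates outside the raster are rejected", {
  pts <- data.frame(x = c(10, 20), y = c(10, 20), cover = c(10, 20))
  expect_error(render_spectral_scene(pts, nrow_px = 2, ncol_px = 2,
                                     origin = c(500, 600)),
               "outside")
})

test_that("extracted tillage index tracks cover at the default noise level", {
  set.seed(33)
  n <- 251
  pts <- data.frame(x = stats::runif(n, 0, 3000),
                    y = stats::runif(n, 0, 3000),
                    cover = lt_quantile(stats::runif(n)),
                    soil = sample(c("cambisol", "leptosol", "luvisol",
                                    "vertisol"), n, TRUE,
                                  c(0.146, 0.255, 0.207, 0.392)))
  sc <- render_spectral_scene(pts, seed = 34)
  nd <- scale_ndti(compute_ndti(sc))
  v <- extract_plot_value(nd, sc$geotransform, pts)
  expect_gt(cor(pts$cover, v, method = "spearman"), 0.5)
})
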