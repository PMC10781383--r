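counts_image <- function(arr) multiband_image(arr, kind = "counts")

test_that("panel-ratio calibration: identity and illumination invariance", {
  a <- array(1000, c(10, 12, 6))
  img <- counts_image(a)
  r <- calibrate(img, c(1, 3, 1, 4), panel_reflectance = rep(1, 6))
  expect_equal(r$data, array(1, c(10, 12, 6)))
  expect_equal(r$kind, "reflectance")
  # halving every count (panel included) leaves reflectance unchanged
  a2 <- array(runif(10 * 12 * 6, 100, 4000), c(10, 12, 6))
  r1 <- calibrate(counts_image(a2), c(1, 3, 1, 4))
  r2 <- calibrate(counts_image(a2 / 2), c(1, 3, 1, 4))
  expect_equal(r1$data, r2$data, tolerance = 1e-12)
})

test_that("calibration rejects bad panels and non-count inputs", {
  a <- array(0, c(5, 5, 6)); a[1, 1, ] <- 0
  expect_error(calibrate(counts_image(a), c(1, 2, 1, 2)), "zero panel")
  b <- array(10, c(5, 5, 6))
  expect_error(calibrate(counts_image(b), c(4, 2, 1, 2)), "rectangle")
  expect_error(calibrate(counts_image(b), c(1, 9, 1, 2)), "rectangle")
  r <- calibrate(counts_image(b), c(1, 2, 1, 2))
  expect_error(calibrate(r, c(1, 2, 1, 2)), "counts image")
})

test_that("segmentation follows the strict 840-nm threshold rule", {
  a <- array(0.24, c(20, 20, 6))
  expect_warning(ls0 <- segment_leaves(multiband_image(a, kind = "reflectance")),
                 "empty")
  expect_equal(nrow(ls0$spectra), 0)
  a[5:14, 3:12, 6] <- 0.5   # one 100-pixel blob, but background at 0.24 < thr
  a[, , 1:5] <- 0.1
  a[5:14, 3:12, 1:5] <- 0.3
  ls1 <- segment_leaves(multiband_image(a, kind = "reflectance"))
  expect_equal(nrow(ls1$spectra), 1)
  expect_equal(ls1$area, 100L)
  expect_equal(unname(ls1$spectra[1, ]), c(rep(0.3, 5), 0.5))
})

test_that("labelling is 8-connected and components are ordered by area", {
  a <- array(0, c(12, 12, 6))
  a[2, 2, 6] <- 0.5; a[3, 3, 6] <- 0.5; a[4, 4, 6] <- 0.5  # diagonal chain
  a[8:11, 2:11, 6] <- 0.5                                  # large block
  ls <- segment_leaves(multiband_image(a, kind = "reflectance"), min_area = 1)
  expect_equal(nrow(ls$spectra), 2)       # the diagonal chain is one leaf
  expect_equal(ls$area, c(40L, 3L))       # labels renumbered by area
  expect_equal(unique(as.vector(ls$labels[8:11, 2:11])), 1L)
})

test_that("components below min_area are removed", {
  a <- array(0, c(12, 12, 6))
  a[2:3, 2:3, 6] <- 0.5       # 4 px
  a[6:10, 6:10, 6] <- 0.5     # 25 px
  ls <- segment_leaves(multiband_image(a, kind = "reflectance"), min_area = 10)
  expect_equal(nrow(ls$spectra), 1)
  expect_equal(ls$area, 25L)
})

test_that("segmentation is idempotent and means match brute force", {
  sc <- render_scene(small_scene_config())
  refl <- calibrate(sc$image, sc$panel, sc$config$panel_reflectance)
  l1 <- segment_leaves(refl, exclude = sc$panel)
  l2 <- segment_leaves(refl, exclude = sc$panel)
  expect_identical(l1$labels, l2$labels)
  for (i in c(1, nrow(l1$spectra))) {
    manual <- vapply(1:6, function(b) mean(refl$data[, , b][l1$labels == i]), 0)
    expect_equal(unname(l1$spectra[i, ]), manual, tolerance = 1e-12)
  }
})

test_that("segmentation recovers the synthetic leaves and their layers", {
  sc <- render_scene(small_scene_config())
  seg <- segment_scene(sc)
  expect_equal(nrow(seg$leaves$spectra), sc$config$n_leaves)
  idx <- which(sc$truth$label_map > 0)
  matched <- seg$leaves$truth_id[pmax(seg$leaves$labels[idx], 1)]
  matched[seg$leaves$labels[idx] == 0] <- 0L
  expect_gte(mean(matched == sc$truth$label_map[idx]), 0.99)
  expect_equal(seg$leaves$layer,
               sc$truth$leaf_table$layer[seg$leaves$truth_id])
})

test_that("leaf-set artifacts are written in the documented formats", {
  sc <- render_scene(small_scene_config())
  seg <- segment_scene(sc)
  lp <- withr::local_tempfile(fileext = ".tif")
  sp <- withr::local_tempfile(fileext = ".csv")
  write_leaf_set(seg$leaves, lp, sp)
  back <- round(tiff::readTIFF(lp) * 65535)
  expect_equal(max(back), sc$config$n_leaves)
  df <- read.csv(sp)
  expect_equal(names(df), c("leaf_id", "area_px", paste0("R", band_centers)))
  expect_equal(nrow(df), sc$config$n_leaves)
})
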