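test_that("pigment draws respect the configured ranges and statistics", {
  pig <- sample_pigments(scene_config())
  expect_equal(nrow(pig), 64)
  expect_true(all(pig$chl_ab >= 2.35 & pig$chl_ab <= 54.25))
  expect_true(all(pig$car >= 2.12 & pig$car <= 9.54))
  expect_lt(abs(mean(pig$chl_ab) - 26.96), 5)  # within 3 SE of the target mean
  # canopy-layer ordering: upper mean below lower mean
  m <- tapply(pig$chl_ab, pig$layer, mean)
  expect_lt(m[["upper"]], m[["lower"]])
  expect_gt(cor(pig$chl_ab, pig$car), 0.5)
})

test_that("pigment sampling is seed-deterministic", {
  expect_identical(sample_pigments(scene_config(seed = 5)),
                   sample_pigments(scene_config(seed = 5)))
  expect_false(identical(sample_pigments(scene_config(seed = 5))$chl_ab,
                         sample_pigments(scene_config(seed = 6))$chl_ab))
})

test_that("infeasible truncation bounds raise a config error", {
  expect_error(sample_pigments(scene_config(chl_range = c(1000, 1001))),
               "infeasible")
})

test_that("reflectance law: zero-absorber limit, monotonicity, flat NIR", {
  r0 <- reflectance_model(0, 0)
  expect_equal(unname(r0), c(0.10, 0.55, 0.50, 0.60, 0.62, 0.62))
  chl <- seq(0, 50, by = 5)
  R <- reflectance_model(chl, rep(5, length(chl)))
  for (b in c("Green", "Red", "Edge1")) {
    expect_true(all(diff(R[, b]) < 0), label = paste("decreasing at", b))
  }
  expect_equal(diff(range(R[, "NIR"])), 0)   # NIR independent of pigments
  expect_true(all(R > 0 & R <= 1))
  expect_error(reflectance_model(-1, 0), ">= 0")
})

test_that("rendering is bit-identical under a fixed seed and varies across seeds", {
  s1 <- render_scene(small_scene_config())
  s2 <- render_scene(small_scene_config())
  expect_identical(s1$image$data, s2$image$data)
  expect_identical(s1$truth, s2$truth)
  s3 <- render_scene(small_scene_config(seed = 43))
  expect_false(identical(s1$truth$label_map, s3$truth$label_map))
})

test_that("ground truth is self-consistent: labels, masked means, zero outside", {
  sc <- render_scene(small_scene_config())
  lab <- sc$truth$label_map
  expect_equal(sort(unique(as.vector(lab[lab > 0]))), 1:9)
  expect_true(all(sc$truth$chl_map[lab == 0] == 0))
  for (i in c(1, 5, 9)) {
    expect_equal(mean(sc$truth$chl_map[lab == i]),
                 sc$truth$leaf_table$chl_ab[i])
    expect_equal(mean(sc$truth$car_map[lab == i]),
                 sc$truth$leaf_table$car[i])
  }
})

test_that("with all distortions off, calibration inverts rendering exactly", {
  sc <- render_scene(clean_scene_config())
  refl <- calibrate(sc$image, sc$panel, sc$config$panel_reflectance)
  # panel pixels recover the panel reflectance exactly
  pr <- refl$data[sc$panel["r0"]:sc$panel["r1"], sc$panel["c0"]:sc$panel["c1"], ]
  for (b in 1:6) {
    expect_equal(max(abs(pr[, , b] - sc$config$panel_reflectance[b])), 0)
  }
  # per-leaf mean spectra reproduce the reflectance law of the leaf-mean pigments
  tab <- sc$truth$leaf_table
  expected <- reflectance_model(tab$chl_ab, tab$car)
  got <- leaf_mean_spectra(sc$truth$label_map, refl)
  expect_lt(max(abs(got - expected)), 1e-6)
})

test_that("840-nm separation holds under default distortion settings", {
  sc <- render_scene(small_scene_config())
  refl <- calibrate(sc$image, sc$panel, sc$config$panel_reflectance)
  nir <- refl$data[, , 6]
  lab <- sc$truth$label_map
  expect_true(all(nir[lab > 0] > 0.25))
  bg <- lab == 0
  bg[sc$panel["r0"]:sc$panel["r1"], sc$panel["c0"]:sc$panel["c1"]] <- FALSE
  expect_true(all(nir[bg] < 0.25))
})

test_that("scene serialization writes the documented artifact set", {
  sc <- render_scene(small_scene_config())
  d <- withr::local_tempdir()
  write_scene(sc, d)
  expect_true(all(file.exists(file.path(d, c("scene_counts.tif",
                                             "truth_maps.tif",
                                             "leaf_table.csv",
                                             "manifest.yaml")))))
  back <- read_multiband_tiff(file.path(d, "scene_counts.tif"), "counts")
  expect_lt(max(abs(back$data - sc$image$data)), 1.5)  # 16-bit quantisation
  man <- yaml::read_yaml(file.path(d, "manifest.yaml"))
  expect_equal(man$seed, 42)
})
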