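test_that("generated B-scans have the configured geometry", {
  cfg <- synth_config()
  img <- generate_bscan(cfg, "A", seed = 1)
  expect_identical(dim(img), c(512L, 512L))
  expect_true(all(img >= 0 & img <= 255))
  expect_error(generate_bscan(cfg, "E", seed = 1), "unknown class")
  expect_error(synth_config(image_height = 0), "positive")
  expect_error(synth_config(nacre_thickness = 600), "fit inside")
})

test_that("zero-signal configuration yields an all-zero image", {
  zero <- speckle_params(mean_intensity = 0, speckle_contrast = 0)
  cfg <- synth_config(background_noise_sigma = 0,
                      class_params = list(A = zero, B = zero,
                                          C = zero, D = zero))
  img <- generate_bscan(cfg, "B", seed = 3)
  expect_true(all(img == 0L))
})

test_that("contrast zero makes equal-depth band profiles constant", {
  p <- speckle_params(speckle_contrast = 0, mean_intensity = 150)
  cfg <- synth_config(surface_curvature = 0, background_noise_sigma = 0,
                      class_params = list(A = p, B = p, C = p, D = p))
  img <- generate_bscan(cfg, "A", seed = 2)
  surf <- ceiling(attr(img, "surface")[1])
  for (depth in c(0, 50, 150))
    expect_lte(diff(range(img[surf + depth, ])), 1)  # within clipping/rounding
})

test_that("datasets are balanced, sized and bit-reproducible", {
  cfg <- small_cfg()
  ds <- generate_dataset(cfg, 29, seed = 7)
  expect_length(ds$images, 116)
  expect_equal(unname(table(ds$labels)), rep(29L, 4), ignore_attr = TRUE)

  ds_small <- generate_dataset(cfg, 1, seed = 7)
  ds_small2 <- generate_dataset(cfg, 1, seed = 7)
  expect_identical(lapply(ds_small$images, unclass),
                   lapply(ds_small2$images, unclass))
  ds_other <- generate_dataset(cfg, 1, seed = 8)
  expect_false(identical(unclass(ds_small$images[[1]]),
                         unclass(ds_other$images[[1]])))
  expect_error(generate_dataset(cfg, 0), "n_per_class")
})

test_that("measured speckle contrast tracks the requested contrast", {
  # mean gray 60 keeps the speckle tail inside the 8-bit range, so the
  # measurement is not biased by clipping
  for (target in c(0.1, 0.4, 0.8)) {
    p <- speckle_params(speckle_contrast = target, mean_intensity = 60,
                        depth_decay = 0)
    cfg <- synth_config(surface_curvature = 0, background_noise_sigma = 0,
                        surface_apex_row = 40, nacre_thickness = 400,
                        class_params = list(A = p, B = p, C = p, D = p))
    img <- generate_bscan(cfg, "A", seed = 101)
    patch <- img[60:187, 100:227] * 1.0  # 128x128 inside the band, no decay
    measured <- sd(patch) / mean(patch)
    expect_lt(abs(measured - target) / target, 0.15)
  }
})

test_that("texture autocorrelation half-width grows with correlation length", {
  half_width <- function(len) {
    p <- speckle_params(speckle_contrast = 0.5, mean_intensity = 150,
                        depth_decay = 0, correlation_length_lateral = len)
    cfg <- synth_config(surface_curvature = 0, background_noise_sigma = 0,
                        surface_apex_row = 40, nacre_thickness = 400,
                        class_params = list(A = p, B = p, C = p, D = p))
    img <- generate_bscan(cfg, "A", seed = 55)
    patch <- img[60:187, 60:315] * 1.0
    acf_lag <- sapply(1:20, function(l)
      cor(as.vector(patch[, 1:(ncol(patch) - l)]),
          as.vector(patch[, (l + 1):ncol(patch)])))
    which(acf_lag < exp(-1))[1]
  }
  hw <- sapply(c(1.5, 3, 6), half_width)
  expect_true(all(diff(hw) > 0))
})

test_that("the topmost band row follows the quadratic surface model", {
  p <- speckle_params(speckle_contrast = 0, mean_intensity = 200)
  cfg <- synth_config(background_noise_sigma = 0,
                      class_params = list(A = p, B = p, C = p, D = p))
  img <- generate_bscan(cfg, "A", seed = 4)
  top <- apply(img, 2, function(col) which(col > 0)[1])
  expect_true(all(abs(top - ceiling(attr(img, "surface"))) <= 1))
})

test_that("write_dataset emits PNGs and a complete manifest", {
  dir <- withr::local_tempdir()
  cfg <- small_cfg()
  ds <- generate_dataset(cfg, 1, seed = 5)
  man <- write_dataset(ds, cfg, dir)
  expect_setequal(man$label, c("A", "B", "C", "D"))
  expect_true(all(file.exists(file.path(dir, man$filename))))
  expect_true(all(c("speckle_contrast", "correlation_length_lateral")
                  %in% names(man)))
  back <- read_bscan(file.path(dir, man$filename[1]))
  expect_identical(unclass(back)[, ], unclass(ds$images[[1]])[, ],
                   ignore_attr = TRUE)
})
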