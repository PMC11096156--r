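test_that("background statistics follow the top-30-row definition", {
  img <- matrix(0L, 40, 20)
  expect_equal(unclass(background_stats(img))[c("mu", "sigma", "threshold")],
               list(mu = 0, sigma = 0, threshold = 0))

  img7 <- matrix(7L, 40, 20)
  expect_equal(background_stats(img7)$threshold, 7)

  # alternating 0/10 checker over the 30-row block: mu 5, sigma 5
  chk <- matrix(0L, 40, 20)
  chk[1:30, ] <- (row(chk[1:30, ]) + col(chk[1:30, ])) %% 2 * 10L
  st <- background_stats(chk)
  expect_equal(st$mu, 5)
  expect_equal(st$sigma, 5)
  expect_equal(st$threshold, 15)

  expect_error(background_stats(matrix(0, 10, 10)), "fewer than 30")
})

test_that("denoising zeroes at-or-below-threshold pixels only", {
  img <- matrix(c(10L, 15L, 16L), 31, 3, byrow = TRUE)
  out <- denoise(img, list(threshold = 15))
  expect_equal(unique(out[, 1]), 0L)
  expect_equal(unique(out[, 2]), 0L)
  expect_equal(unique(out[, 3]), 16L)
  expect_true(all(denoise(matrix(0L, 40, 5), list(threshold = 0)) == 0L))
  # never increases a pixel, never touches supra-threshold pixels
  set.seed(1)
  r <- matrix(sample(0:255, 40 * 40, TRUE), 40, 40)
  d <- denoise(r, list(threshold = 30))
  expect_true(all(d <= r))
  expect_identical(d[r > 30], r[r > 30])
})

test_that("the background threshold removes almost all background noise", {
  cfg <- synth_config()
  img <- generate_bscan(cfg, "B", seed = 21)
  den <- denoise(img, background_stats(img))
  bg <- !attr(img, "band_mask")
  expect_lte(mean(den[bg] > 0), 0.05)
})

test_that("rough edge detection finds a flat surface within one pixel", {
  img <- flat_band_image(edge_row = 100)
  fit <- detect_rough_edge(img)
  expect_true(all(abs(fit$rough_edge - 100) <= 1, na.rm = TRUE))
  expect_lte(mean(is.na(fit$rough_edge)), 0.1)
  expect_error(detect_rough_edge(matrix(0L, 200, 100)), "surface not found")
})

test_that("rough edge tracks the generating quadratic on synthetic scans", {
  img <- generate_bscan(synth_config(), "C", seed = 31)
  den <- denoise(img, background_stats(img))
  fit <- detect_rough_edge(den)
  err <- abs(fit$rough_edge - attr(img, "surface"))
  expect_gte(mean(err <= 2, na.rm = TRUE), 0.95)
})

test_that("surface fitting is exact on a parabola and robust to an outlier", {
  cols <- 1:512
  parab <- 100 + 0.001 * (cols - 256)^2
  rough <- structure(list(rough_edge = parab), class = "surface_fit")
  fit <- fit_surface(rough, degree = 2)
  expect_lt(fit$residual_rms, 1e-8)
  expect_equal(fit$fitted_edge, parab, tolerance = 1e-8)

  flat <- rep(100, 512); flat[200] <- 150
  fit2 <- fit_surface(structure(list(rough_edge = flat),
                                class = "surface_fit"), degree = 2)
  expect_true(all(abs(fit2$fitted_edge - 100) <= 1))

  # missing columns are excluded from the fit, then filled by the polynomial
  holey <- parab; holey[seq(1, 512, by = 3)] <- NA
  fit3 <- fit_surface(structure(list(rough_edge = holey),
                                class = "surface_fit"), degree = 2)
  expect_equal(fit3$fitted_edge, parab, tolerance = 1e-8)

  expect_error(fit_surface(structure(list(rough_edge = c(1, 2, rep(NA, 20))),
                                     class = "surface_fit"), degree = 2),
               "underdetermined")
})

test_that("flattening obeys the integer-shift contract", {
  img <- flat_band_image(h = 200, w = 10, edge_row = 100)
  fit <- list(fitted_edge = rep(100, 10))
  out <- flatten_bscan(img, fit, target_row = 100)
  expect_identical(out[100:200, ], img[100:200, ])
  expect_true(all(out[1:99, ] == 0L))

  one <- matrix(0L, 200, 1); one[90:200, 1] <- 50L
  shifted <- flatten_bscan(one, list(fitted_edge = 90), target_row = 100)
  expect_true(all(shifted[100:200, 1] == 50L))
  expect_true(all(shifted[1:99, 1] == 0L))

  expect_error(flatten_bscan(one, list(fitted_edge = 500), target_row = 100),
               "out of frame")
})

test_that("flattening a synthetic parabolic surface leaves a level edge", {
  img <- generate_bscan(synth_config(), "B", seed = 41)
  st <- background_stats(img)
  den <- denoise(img, st)
  fit <- fit_surface(detect_rough_edge(den), degree = 2)
  expect_lte(max(abs(fit$fitted_edge - attr(img, "surface"))), 2)
  flat <- flatten_bscan(den, fit, target_row = 20)
  refit <- detect_rough_edge(flat)
  expect_lte(sd(refit$rough_edge, na.rm = TRUE), 1)
  # idempotence: flattening the flattened image shifts columns by <= 1 px
  refit2 <- fit_surface(refit, degree = 2)
  expect_true(all(abs(round(20 - refit2$fitted_edge)) <= 1))
})

test_that("ROI cropping uses the documented placement arithmetic", {
  flat <- matrix(seq_len(512 * 512), 512, 512)
  roi <- crop_roi(flat, target_row = 20, offset = 2)
  expect_identical(dim(roi$pixels), c(128L, 128L))
  expect_equal(roi$origin_row, 22)
  expect_equal(roi$origin_col, 193)
  expect_identical(roi$pixels, flat[22:149, 193:320])

  short <- matrix(0L, 140, 512)
  expect_error(crop_roi(short, target_row = 20, offset = 2), "exceeds")
  narrow <- matrix(0L, 512, 100)
  expect_error(crop_roi(narrow, target_row = 20, offset = 2), "exceeds")
})

test_that("the end-to-end ROI contains only nacre-band texture", {
  img <- generate_bscan(synth_config(), "D", seed = 51)
  loc <- locate_roi(img)
  expect_identical(dim(loc$roi$pixels), c(128L, 128L))
  # flatten the generator's band mask with the same fit and crop the same
  # window: essentially every ROI pixel must be band-labeled
  mask <- flatten_bscan(1L * attr(img, "band_mask"), loc$fit,
                        target_row = 20)
  mask_roi <- crop_roi(mask, target_row = 20, offset = 2)
  expect_lte(mean(mask_roi$pixels == 0), 0.01)
})
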