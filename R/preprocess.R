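#' Background statistics of a B-scan
#'
#' The top 30 rows of a pearl B-scan lie above the nacre surface and contain
#' only background noise. Their mean and standard deviation define the hard
#' denoising threshold `mu + 2 * sigma`. `sigma` is the population standard
#' deviation of the 30-row block.
#'
#' @param img B-scan matrix (rows = depth, row 1 shallowest).
#' @param n_rows number of top rows treated as pure background.
#' @return List of class `background_stats` with `mu`, `sigma`, `threshold`.
#' @export
background_stats <- function(img, n_rows = 30L) {
  if (nrow(img) < n_rows)
    stop("image has fewer than ", n_rows, " rows", call. = FALSE)
  top <- as.numeric(img[seq_len(n_rows), ])
  mu <- mean(top)
  sigma <- sqrt(mean((top - mu)^2))
  structure(list(mu = mu, sigma = sigma, threshold = mu + 2 * sigma),
            class = "background_stats")
}

#' Hard-threshold denoising
#'
#' Zeroes every pixel at or below the background threshold; pixels above it
#' are untouched.
#'
#' @param img B-scan matrix.
#' @param stats a [background_stats()] result (or any list with
#'   `$threshold`).
#' @return Denoised matrix of the same shape and attributes.
#' @export
denoise <- function(img, stats) {
  out <- img
  out[out <= stats$threshold] <- 0L
  out
}

#' Rough surface edge per column
#'
#' Runs the Canny operator on a (denoised) B-scan and takes, per column, the
#' shallowest edge pixel as the rough nacre surface. Columns without any
#' edge pixel are `NA`.
#'
#' @param img denoised B-scan matrix.
#' @param sigma Gaussian smoothing std for the Canny operator.
#' @return List of class `surface_fit` with `rough_edge` (numeric vector,
#'   one row index or `NA` per column) populated.
#' @export
detect_rough_edge <- function(img, sigma = 2) {
  edges <- canny_edges(img, sigma = sigma)
  rough <- apply(edges, 2, function(col) {
    i <- which(col)
    if (length(i)) i[1] else NA_real_
  })
  if (mean(is.na(rough)) > 0.5)
    stop("surface not found: no edge in more than half of the columns",
         call. = FALSE)
  structure(list(rough_edge = rough, poly_coeffs = NULL,
                 fitted_edge = NULL, residual_rms = NULL),
            class = "surface_fit")
}

#' Polynomial fit of the rough surface edge
#'
#' Least-squares fit of row as a polynomial in column over the non-missing
#' columns; missing columns are filled in by the fitted polynomial.
#'
#' @param rough a `surface_fit` with `rough_edge` populated.
#' @param degree polynomial degree; 2 suits the locally spherical cap of a
#'   pearl seen in a B-scan.
#' @return The `surface_fit` with `poly_coeffs` (ascending powers),
#'   `fitted_edge` and `residual_rms` populated.
#' @export
fit_surface <- function(rough, degree = 2L) {
  y <- rough$rough_edge
  ok <- which(!is.na(y))
  if (length(ok) < degree + 1L)
    stop("underdetermined surface fit: need at least ", degree + 1L,
         " detected columns", call. = FALSE)
  x <- seq_along(y)
  X <- outer(x, 0:degree, "^")
  cf <- lm.fit(X[ok, , drop = FALSE], y[ok])$coefficients
  fitted_edge <- drop(X %*% cf)
  rough$poly_coeffs <- unname(cf)
  rough$fitted_edge <- fitted_edge
  rough$residual_rms <- sqrt(mean((fitted_edge[ok] - y[ok])^2))
  rough
}

#' Flatten a B-scan along its fitted surface
#'
#' Removes remaining background (pixels above the fitted edge), then shifts
#' each column by an integer number of rows so that the fitted edge lies on
#' the horizontal line `target_row`. Integer shifts preserve the raw speckle
#' pattern; vacated pixels are zero-filled.
#'
#' @param img denoised B-scan matrix.
#' @param fit a `surface_fit` with `fitted_edge` populated.
#' @param target_row row on which the surface is placed after flattening.
#' @return Flattened matrix of the same shape.
#' @export
flatten_bscan <- function(img, fit, target_row = 20L) {
  fe <- fit$fitted_edge
  h <- nrow(img); w <- ncol(img)
  stopifnot(length(fe) == w)
  shifts <- round(target_row - fe)
  if (any(abs(shifts) >= h))
    stop("flattening shift moves the nacre band entirely out of frame",
         call. = FALSE)
  out <- matrix(0L, h, w)
  for (j in seq_len(w)) {
    col <- img[, j]
    above <- seq_len(h) < fe[j]
    col[above] <- 0L
    s <- shifts[j]
    if (s >= 0) out[(1 + s):h, j] <- col[1:(h - s)]
    else out[1:(h + s), j] <- col[(1 - s):h]
  }
  out
}

#' Crop the 128x128 region of interest
#'
#' Takes the laterally centered 128x128 patch starting `offset` rows below
#' the flattened surface line — the "middle upper part" of the nacre band,
#' where the signal is strongest.
#'
#' @param flat flattened B-scan matrix.
#' @param target_row flattened surface row (as passed to [flatten_bscan()]).
#' @param offset rows between the surface line and the top of the ROI.
#' @param size ROI side length in pixels.
#' @return List of class `roi_patch` with `pixels` (`size` x `size`
#'   matrix), `origin_row`, `origin_col`.
#' @export
crop_roi <- function(flat, target_row = 20L, offset = 2L, size = 128L) {
  h <- nrow(flat); w <- ncol(flat)
  r0 <- target_row + offset
  c0 <- w %/% 2L - (size %/% 2L - 1L)
  if (r0 < 1 || r0 + size - 1L > h || c0 < 1 || c0 + size - 1L > w)
    stop("ROI (rows ", r0, "-", r0 + size - 1L, ", cols ", c0, "-",
         c0 + size - 1L, ") exceeds the ", h, "x", w, " image", call. = FALSE)
  structure(list(pixels = flat[r0:(r0 + size - 1L), c0:(c0 + size - 1L)],
                 origin_row = r0, origin_col = c0),
            class = "roi_patch")
}

#' Automated target location, end to end
#'
#' Background thresholding, Canny rough-edge detection, polynomial surface
#' fit, flattening and ROI extraction in one call.
#'
#' @inheritParams background_stats
#' @inheritParams fit_surface
#' @inheritParams crop_roi
#' @param canny_sigma smoothing std for the edge detector.
#' @return List of class `located_target` with the `roi_patch`, the
#'   `surface_fit`, the `background_stats` and the flattened image.
#' @export
locate_roi <- function(img, degree = 2L, target_row = 20L, offset = 2L,
                       size = 128L, canny_sigma = 2) {
  stats <- background_stats(img)
  den <- denoise(img, stats)
  fit <- fit_surface(detect_rough_edge(den, sigma = canny_sigma),
                     degree = degree)
  flat <- flatten_bscan(den, fit, target_row = target_row)
  roi <- crop_roi(flat, target_row = target_row, offset = offset, size = size)
  structure(list(roi = roi, fit = fit, stats = stats, flattened = flat),
            class = "located_target")
}
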