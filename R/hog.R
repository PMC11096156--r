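#' HOG feature block (18 values)
#'
#' Histogram of oriented gradients with the whole ROI as a single block:
#' gradients by central differences (replicated borders), unsigned
#' orientation folded to 0-180 degrees, 9 bins of 20 degrees with
#' magnitude-weighted hard assignment, one histogram per `cell_size` x
#' `cell_size` cell (1024 cells on a 128x128 ROI). No block normalization.
#' The feature is the per-bin mean over cells followed by the per-bin
#' standard deviation over cells.
#'
#' @param roi ROI matrix or `roi_patch`; side lengths must be multiples of
#'   `cell_size` (the pipeline uses 128x128).
#' @param cell_size cell side in pixels.
#' @param bins orientation bins over 0-180 degrees.
#' @return Named numeric vector: 9 bin means then 9 bin standard
#'   deviations.
#' @export
extract_hog <- function(roi, cell_size = 4L, bins = 9L) {
  x <- as_roi_matrix(roi)
  h <- nrow(x); w <- ncol(x)
  if (h %% cell_size != 0 || w %% cell_size != 0)
    stop("HOG needs ROI dimensions divisible by the cell size (",
         cell_size, "), got ", h, "x", w, call. = FALSE)
  H <- hog_cell_histograms(x, cell_size, bins)
  c(setNames(colMeans(H), sprintf("hog_bin%d_mean", seq_len(bins))),
    setNames(apply(H, 2, sd), sprintf("hog_bin%d_std", seq_len(bins))))
}

#' Per-cell orientation histograms
#'
#' @inheritParams extract_hog
#' @return Matrix with one row per cell (row-major over the cell grid) and
#'   one column per orientation bin; entries are summed gradient
#'   magnitudes.
#' @export
hog_cell_histograms <- function(roi, cell_size = 4L, bins = 9L) {
  x <- as_roi_matrix(roi)
  h <- nrow(x); w <- ncol(x)
  gx <- (x[, c(2:w, w)] - x[, c(1, 1:(w - 1))]) / 2
  gy <- (x[c(2:h, h), ] - x[c(1, 1:(h - 1)), ]) / 2
  mag <- sqrt(gx^2 + gy^2)
  theta <- (atan2(gy, gx) * 180 / pi) %% 180
  bin <- pmin(floor(theta / (180 / bins)) + 1L, bins)

  cr <- (row(x) - 1L) %/% cell_size
  cc <- (col(x) - 1L) %/% cell_size
  cell <- cr * (w %/% cell_size) + cc + 1L  # row-major cell index
  n_cells <- (h %/% cell_size) * (w %/% cell_size)
  H <- tapply(as.numeric(mag),
              list(factor(cell, seq_len(n_cells)), factor(bin, seq_len(bins))),
              sum, default = 0)
  matrix(H, n_cells, bins)
}
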