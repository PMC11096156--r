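#' The 14 LBP neighbor/radius pairs
#'
#' @return Data frame with columns `P` (neighbors) and `R` (radius).
#' @export
lbp_pairs <- function() {
  data.frame(P = c(4, 4, 8, 8, 8, 12, 12, 12, 12, 16, 16, 16, 16, 16),
             R = c(1, 2, 1, 2, 3, 1, 2, 3, 4, 1, 2, 3, 4, 5))
}

# Bilinear sample of x at (row + dr, col + dc) for all interior pixels at
# margin m. dr, dc are scalar offsets.
bilinear_shift <- function(x, rows, cols, dr, dc) {
  r0 <- floor(dr); c0 <- floor(dc)
  fr <- dr - r0; fc <- dc - c0
  s <- function(a, b) x[rows + a, cols + b, drop = FALSE]
  # zero-weight corners are skipped: on exact-integer offsets the +1
  # neighbor can lie outside the image
  v <- (1 - fr) * (1 - fc) * s(r0, c0)
  if (fc > 0) v <- v + (1 - fr) * fc * s(r0, c0 + 1)
  if (fr > 0) v <- v + fr * (1 - fc) * s(r0 + 1, c0)
  if (fr > 0 && fc > 0) v <- v + fr * fc * s(r0 + 1, c0 + 1)
  v
}

#' LBP code image
#'
#' Plain (non-uniform) local binary pattern codes: the P neighbors on a
#' circle of radius R are sampled with bilinear interpolation (offsets
#' within 1e-6 of the grid are snapped) and compared to the center with the
#' convention neighbor >= center => bit 1; bit k has weight 2^k, neighbor 0
#' lying in the +column direction and the ring walked counterclockwise in
#' image coordinates. Only pixels with the full ring inside the image are
#' coded.
#'
#' @param x grayscale matrix.
#' @param P neighbors on the ring.
#' @param R ring radius in pixels.
#' @return Numeric matrix of codes, `(nrow - 2m) x (ncol - 2m)` with
#'   `m = ceiling(R)`.
#' @export
lbp_code_image <- function(x, P, R) {
  x <- as_roi_matrix(x)
  m <- ceiling(R)
  h <- nrow(x); w <- ncol(x)
  if (h <= 2 * m || w <= 2 * m)
    stop("image too small for LBP radius ", R, call. = FALSE)
  rows <- (m + 1):(h - m); cols <- (m + 1):(w - m)
  center <- x[rows, cols, drop = FALSE]
  code <- matrix(0, length(rows), length(cols))
  for (k in 0:(P - 1)) {
    a <- 2 * pi * k / P
    dr <- -R * sin(a)  # neighbor 0 at +col, walking counterclockwise (up first)
    dc <- R * cos(a)
    if (abs(dr - round(dr)) < 1e-6) dr <- round(dr)
    if (abs(dc - round(dc)) < 1e-6) dc <- round(dc)
    v <- bilinear_shift(x, rows, cols, dr, dc)
    code <- code + (v >= center - 1e-7) * 2^k
  }
  code
}

#' LBP feature block (28 values)
#'
#' The whole ROI is one LBP cell: for each of the 14 neighbor/radius pairs
#' the mean and standard deviation of the code image are emitted.
#'
#' @param roi ROI matrix or `roi_patch`.
#' @param pairs data frame of `(P, R)` pairs, see [lbp_pairs()].
#' @return Named numeric vector: 14 means then 14 standard deviations.
#' @export
extract_lbp <- function(roi, pairs = lbp_pairs()) {
  x <- as_roi_matrix(roi)
  codes <- lapply(seq_len(nrow(pairs)), function(i)
    lbp_code_image(x, pairs$P[i], pairs$R[i]))
  nm <- sprintf("lbp_p%d_r%d", pairs$P, pairs$R)
  c(setNames(vapply(codes, mean, numeric(1)), paste0(nm, "_mean")),
    setNames(vapply(codes, sd, numeric(1)), paste0(nm, "_std")))
}
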