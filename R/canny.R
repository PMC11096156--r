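# Canny edge detection on a grayscale matrix (rows = depth).
# Gaussian smoothing, Sobel gradients, non-maximum suppression along the
# quantized gradient direction, then hysteresis with thresholds derived
# from the Otsu level of the gradient-magnitude histogram (high = otsu,
# low = 0.5 * high). Connected weak/strong components are resolved with
# EBImage::bwlabel (8-connectivity).

shift_mat <- function(m, dr, dc, fill = 0) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  rs <- max(1, 1 + dr):min(h, h + dr)
  cs <- max(1, 1 + dc):min(w, w + dc)
  out[rs, cs] <- m[rs - dr, cs - dc, drop = FALSE]
  out
}

#' Canny edge map
#'
#' @param img numeric matrix (gray levels; rows index depth).
#' @param sigma Gaussian smoothing std in pixels.
#' @param low_frac,high_frac hysteresis thresholds as fractions of the Otsu
#'   level of the gradient magnitude.
#' @return Logical matrix of edge pixels.
#' @export
canny_edges <- function(img, sigma = 2, low_frac = 0.5, high_frac = 1) {
  img <- unclass(img) * 1.0
  sz <- 2L * ceiling(3 * sigma) + 1L
  g <- EBImage::filter2(img, EBImage::makeBrush(sz, "Gaussian", sigma = sigma),
                        boundary = "replicate")
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)  # d/dcol
  gx <- EBImage::filter2(g, kx, boundary = "replicate")
  gy <- EBImage::filter2(g, t(kx), boundary = "replicate")
  mag <- sqrt(gx^2 + gy^2)
  if (max(mag) == 0) return(matrix(FALSE, nrow(img), ncol(img)))

  ang <- (atan2(gy, gx) * 180 / pi) %% 180
  sector <- findInterval(ang, c(22.5, 67.5, 112.5, 157.5)) %% 4  # 0,45,90,135

  # neighbor pair along the gradient direction for each sector
  # sector 0: horizontal gradient -> compare left/right columns
  # sector 1: 45 deg (gy, gx same sign quadrant) -> diagonal neighbors
  # sector 2: vertical gradient -> compare rows above/below
  # sector 3: 135 deg -> other diagonal
  n1 <- shift_mat(mag, 0, 1);  n2 <- shift_mat(mag, 0, -1)
  d1 <- shift_mat(mag, 1, 1);  d2 <- shift_mat(mag, -1, -1)
  v1 <- shift_mat(mag, 1, 0);  v2 <- shift_mat(mag, -1, 0)
  e1 <- shift_mat(mag, 1, -1); e2 <- shift_mat(mag, -1, 1)
  keep <- (sector == 0 & mag >= n1 & mag >= n2) |
          (sector == 1 & mag >= d1 & mag >= d2) |
          (sector == 2 & mag >= v1 & mag >= v2) |
          (sector == 3 & mag >= e1 & mag >= e2)
  nms <- ifelse(keep, mag, 0)

  high <- EBImage::otsu(mag / max(mag), range = c(0, 1)) * max(mag) * high_frac
  low <- low_frac * high
  strong <- nms >= high
  weak <- nms >= low
  if (!any(strong)) return(strong)
  lab <- EBImage::bwlabel(weak)
  keep_ids <- unique(lab[strong])
  matrix(lab %in% keep_ids[keep_ids > 0], nrow(img), ncol(img))
}
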