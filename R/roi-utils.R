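# Shared helpers for the texture bank.

# Accept a roi_patch, an EBImage Image, or a plain matrix; return a plain
# numeric matrix.
as_roi_matrix <- function(roi) {
  if (inherits(roi, "roi_patch")) roi <- roi$pixels
  m <- unclass(roi)
  if (!is.matrix(m)) m <- as.matrix(m)
  storage.mode(m) <- "double"
  m
}

# Mirror (reflect) padding by p pixels on every side.
pad_reflect <- function(x, p) {
  h <- nrow(x); w <- ncol(x)
  stopifnot(p < h, p < w)
  ri <- c(p:1, 1:h, h:(h - p + 1))
  ci <- c(p:1, 1:w, w:(w - p + 1))
  x[ri, ci, drop = FALSE]
}

# Correlation filtering with reflect padding; kernel dims must be odd.
conv2_reflect <- function(x, kern) {
  p <- max(dim(kern)) %/% 2
  padded <- pad_reflect(x, p)
  out <- EBImage::filter2(padded, kern, boundary = "circular")
  out[(p + 1):(p + nrow(x)), (p + 1):(p + ncol(x)), drop = FALSE]
}
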