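#' Read an 8-bit grayscale B-scan image
#'
#' Reads PNG (via the png package) or TIFF (via the tiff package, if
#' installed) and returns an integer matrix in 0-255 with rows indexing
#' depth. Multi-channel images are averaged to grayscale.
#'
#' @param path image file, `.png`, `.tif` or `.tiff`.
#' @return Integer matrix of gray levels 0-255 with attribute `source_id`
#'   set to the file name.
#' @export
read_bscan <- function(path) {
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("reading TIFF requires the 'tiff' package", call. = FALSE)
      tiff::readTIFF(path)
    },
    stop("unsupported image format: ", ext, call. = FALSE))
  if (length(dim(x)) == 3L) x <- rowMeans(x, dims = 2L)
  m <- matrix(as.integer(round(x * 255)), nrow(x), ncol(x))
  attr(m, "source_id") <- basename(path)
  m
}

#' Write an 8-bit grayscale image as PNG
#'
#' @param img numeric/integer matrix of gray levels 0-255.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_bscan_png <- function(img, path) {
  m <- unclass(img)
  png::writePNG(pmin(pmax(m, 0), 255) / 255, path)
  invisible(path)
}
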