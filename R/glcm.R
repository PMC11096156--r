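#' GLCM descriptor configuration
#'
#' Four second-order statistics (entropy, energy, correlation and inertia,
#' i.e. contrast) evaluated on normalized symmetric co-occurrence matrices
#' at pixel distances 1-10 and the four principal directions, giving
#' 4 statistics x 10 distances = 40 (statistic, distance) combinations.
#' For each combination the statistic's four per-angle values form its
#' "map"; the map's mean and standard deviation enter the feature vector.
#'
#' @param gray_levels quantization bin count applied to the 0-255 ROI.
#' @param distances integer pixel offsets.
#' @param angles directions in degrees.
#' @param statistics statistic names, fixed order.
#' @return List of class `glcm_config`.
#' @export
glcm_config <- function(gray_levels = 16L, distances = 1:10,
                        angles = c(0, 45, 90, 135),
                        statistics = c("entropy", "energy",
                                       "correlation", "contrast")) {
  structure(list(gray_levels = as.integer(gray_levels),
                 distances = as.integer(distances), angles = angles,
                 statistics = statistics),
            class = "glcm_config")
}

# Uniform quantization of gray levels [0, max_gray) into `levels` bins.
quantize_gray <- function(x, levels, max_gray = 256) {
  q <- floor(x * (levels / max_gray))
  pmin(pmax(q, 0), levels - 1L)
}

# Direction in degrees -> (row, col) displacement at distance d.
# Row 1 is the image top, so 45 deg points up-right.
glcm_offset <- function(angle, d) {
  switch(as.character(angle),
         "0"   = c(0, d),
         "45"  = c(-d, d),
         "90"  = c(-d, 0),
         "135" = c(-d, -d),
         stop("unsupported GLCM angle: ", angle, call. = FALSE))
}

# Normalized symmetric co-occurrence matrix of a quantized image.
cooccurrence_matrix <- function(q, levels, dr, dc) {
  h <- nrow(q); w <- ncol(q)
  rs <- seq(max(1, 1 + dr), min(h, h + dr))
  cs <- seq(max(1, 1 + dc), min(w, w + dc))
  i <- q[rs - dr, cs - dc, drop = FALSE]
  j <- q[rs, cs, drop = FALSE]
  counts <- tabulate(i * levels + j + 1L, nbins = levels^2)
  P <- matrix(counts, levels, levels, byrow = TRUE)
  P <- P + t(P)
  P / sum(P)
}

glcm_statistic <- function(P, stat) {
  L <- nrow(P)
  lev <- 0:(L - 1)
  switch(stat,
    entropy = { p <- P[P > 0]; -sum(p * log2(p)) },
    energy = sum(P^2),
    contrast = sum(outer(lev, lev, function(i, j) (i - j)^2) * P),
    correlation = {
      px <- rowSums(P); py <- colSums(P)
      mx <- sum(lev * px); my <- sum(lev * py)
      sx <- sqrt(sum((lev - mx)^2 * px)); sy <- sqrt(sum((lev - my)^2 * py))
      if (sx == 0 || sy == 0) return(0)  # constant image: 0/0 -> 0
      (sum(outer(lev, lev) * P) - mx * my) / (sx * sy)
    },
    stop("unknown GLCM statistic: ", stat, call. = FALSE))
}

#' GLCM feature block (80 values)
#'
#' @param roi 128x128 ROI (a `roi_patch` or plain matrix, gray levels
#'   0-255).
#' @param cfg a [glcm_config()].
#' @return Named numeric vector: 40 per-combination map means followed by
#'   40 map standard deviations, statistic-major / distance-minor.
#' @export
extract_glcm <- function(roi, cfg = glcm_config()) {
  x <- as_roi_matrix(roi)
  if (max(cfg$distances) >= min(dim(x)))
    stop("GLCM distance ", max(cfg$distances),
         " is not smaller than the ROI side", call. = FALSE)
  q <- quantize_gray(x, cfg$gray_levels)
  # one co-occurrence matrix per (distance, angle), shared by all statistics
  mats <- lapply(cfg$distances, function(d)
    lapply(cfg$angles, function(a) {
      off <- glcm_offset(a, d)
      cooccurrence_matrix(q, cfg$gray_levels, off[1], off[2])
    }))
  means <- c(); stds <- c()
  for (stat in cfg$statistics) {
    for (di in seq_along(cfg$distances)) {
      vals <- vapply(mats[[di]], glcm_statistic, numeric(1), stat = stat)
      nm <- sprintf("glcm_%s_d%02d", stat, cfg$distances[di])
      means[paste0(nm, "_mean")] <- mean(vals)
      stds[paste0(nm, "_std")] <- sd(vals)
    }
  }
  c(means, stds)
}
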