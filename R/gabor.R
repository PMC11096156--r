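#' Gabor filter bank configuration
#'
#' Five carrier wavelengths by eight orientations = 40 filters. The
#' Gaussian envelope std follows the wavelength through a fixed spatial
#' bandwidth of one octave (`sigma ~= 0.56 * wavelength`); the envelope is
#' isotropic (aspect ratio 1).
#'
#' @param wavelengths carrier wavelengths in pixels.
#' @param orientations carrier directions in degrees.
#' @param bandwidth spatial-frequency bandwidth in octaves.
#' @param aspect envelope aspect ratio (sigma_y / sigma_x scaling).
#' @return List of class `gabor_config`.
#' @export
gabor_config <- function(wavelengths = c(2, 4, 8, 10, 12),
                         orientations = seq(0, 315, by = 45),
                         bandwidth = 1, aspect = 1) {
  structure(list(wavelengths = wavelengths, orientations = orientations,
                 bandwidth = bandwidth, aspect = aspect),
            class = "gabor_config")
}

gabor_sigma <- function(lambda, bandwidth) {
  lambda / pi * sqrt(log(2) / 2) * (2^bandwidth + 1) / (2^bandwidth - 1)
}

# Quadrature pair of Gabor kernels. x runs along columns, y along rows
# (downwards); cospi/sinpi keep multiples of 90 degrees exact so that
# rotating the ROI by 90 degrees permutes orientations exactly.
gabor_kernel <- function(lambda, theta_deg, bandwidth = 1, aspect = 1) {
  sigma <- gabor_sigma(lambda, bandwidth)
  half <- ceiling(3 * sigma)
  x <- outer(rep(1, 2 * half + 1), (-half):half)        # column offset
  y <- outer((-half):half, rep(1, 2 * half + 1))        # row offset
  ct <- cospi(theta_deg / 180); st <- sinpi(theta_deg / 180)
  xp <- x * ct + y * st
  yp <- -x * st + y * ct
  env <- exp(-(xp^2 + (aspect * yp)^2) / (2 * sigma^2))
  even <- env * cos(2 * pi * xp / lambda)
  odd <- env * sin(2 * pi * xp / lambda)
  even <- even - env * (sum(even) / sum(env))  # remove DC from the real part
  list(even = even, odd = odd)
}

#' Gabor feature block (80 values)
#'
#' Each filter's quadrature response magnitude image
#' `sqrt(even^2 + odd^2)` (reflect padding) is summarized by its mean and
#' standard deviation, wavelength-major / orientation-minor.
#'
#' @param roi ROI matrix or `roi_patch`.
#' @param cfg a [gabor_config()].
#' @return Named numeric vector: 40 magnitude means then 40 standard
#'   deviations.
#' @export
extract_gabor <- function(roi, cfg = gabor_config()) {
  x <- as_roi_matrix(roi)
  means <- c(); stds <- c()
  for (lambda in cfg$wavelengths) {
    for (theta in cfg$orientations) {
      k <- gabor_kernel(lambda, theta, cfg$bandwidth, cfg$aspect)
      mag <- sqrt(conv2_reflect(x, k$even)^2 + conv2_reflect(x, k$odd)^2)
      nm <- sprintf("gabor_w%02d_o%03d", lambda, theta)
      means[paste0(nm, "_mean")] <- mean(mag)
      stds[paste0(nm, "_std")] <- sd(mag)
    }
  }
  c(means, stds)
}
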