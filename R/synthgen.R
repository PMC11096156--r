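#' Speckle parameters for one luster class
#'
#' Describes the multiplicative speckle field painted inside the nacre band
#' of a synthetic B-scan. The field has unit mean; `speckle_contrast` is its
#' standard deviation divided by its mean, and the correlation lengths are
#' the 1/e half-widths of its spatial autocorrelation along depth (axial)
#' and across the scan (lateral).
#'
#' @param mean_intensity mean gray level of the band at the surface (0-255).
#' @param speckle_contrast dimensionless contrast (std/mean) of the
#'   multiplicative field; `0` gives a noise-free band.
#' @param correlation_length_axial,correlation_length_lateral speckle
#'   correlation lengths in pixels (>= 1).
#' @param depth_decay exponential attenuation per pixel of depth.
#' @return An object of class `speckle_params`.
#' @export
speckle_params <- function(mean_intensity = 180,
                           speckle_contrast = 0.4,
                           correlation_length_axial = 1.5,
                           correlation_length_lateral = 2.5,
                           depth_decay = 0.008) {
  stopifnot(speckle_contrast >= 0,
            correlation_length_axial >= 1, correlation_length_lateral >= 1,
            mean_intensity >= 0, mean_intensity <= 255,
            depth_decay >= 0)
  structure(list(mean_intensity = mean_intensity,
                 speckle_contrast = speckle_contrast,
                 correlation_length_axial = correlation_length_axial,
                 correlation_length_lateral = correlation_length_lateral,
                 depth_decay = depth_decay),
            class = "speckle_params")
}

#' Default per-class speckle parameters
#'
#' The four luster grades are separated primarily in speckle contrast (a
#' 2x ladder from A to D) and secondarily in lateral correlation length, so
#' classes are statistically separable by second-order texture while their
#' pixel histograms overlap. Grade A (highest luster) is modeled as the
#' smoothest, most finely correlated band.
#'
#' @return Named list of [speckle_params()], one per grade `A`-`D`.
#' @export
default_class_params <- function() {
  list(
    A = speckle_params(speckle_contrast = 0.1, correlation_length_lateral = 1.5,
                       correlation_length_axial = 1.0),
    B = speckle_params(speckle_contrast = 0.2, correlation_length_lateral = 2.0,
                       correlation_length_axial = 1.2),
    C = speckle_params(speckle_contrast = 0.4, correlation_length_lateral = 3.0,
                       correlation_length_axial = 1.5),
    D = speckle_params(speckle_contrast = 0.8, correlation_length_lateral = 4.5,
                       correlation_length_axial = 2.0)
  )
}

#' Synthetic B-scan generator configuration
#'
#' Geometry and noise settings shared by all classes: the nacre surface is
#' the parabola `row(col) = apex + curvature * (col - width/2)^2` (rows
#' index depth, row 1 shallowest; the cap bulges toward the probe), the band
#' below it is `nacre_thickness` pixels thick, and everything outside the
#' band is rectified Gaussian background noise.
#'
#' @param image_height,image_width image size in pixels.
#' @param surface_apex_row row of the surface at the lateral center.
#' @param surface_curvature quadratic coefficient in pixels^-1.
#' @param nacre_thickness band thickness in pixels.
#' @param background_noise_sigma std of the background noise (gray levels).
#' @param class_params named list of [speckle_params()] keyed by grade.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(image_height = 512L, image_width = 512L,
                         surface_apex_row = 140, surface_curvature = 0.0012,
                         nacre_thickness = 220, background_noise_sigma = 4,
                         class_params = default_class_params()) {
  if (image_height <= 0 || image_width <= 0)
    stop("image dimensions must be positive", call. = FALSE)
  if (surface_apex_row + nacre_thickness >= image_height)
    stop("apex_row + nacre_thickness must fit inside the image", call. = FALSE)
  if (length(class_params) != 4L ||
      !setequal(names(class_params), c("A", "B", "C", "D")))
    stop("class_params must name exactly the four grades A, B, C, D",
         call. = FALSE)
  structure(list(image_height = as.integer(image_height),
                 image_width = as.integer(image_width),
                 surface_apex_row = surface_apex_row,
                 surface_curvature = surface_curvature,
                 nacre_thickness = nacre_thickness,
                 background_noise_sigma = background_noise_sigma,
                 class_params = class_params),
            class = "synth_config")
}

# Separable Gaussian low-pass kernel; sigma = L/2 gives a filtered-noise
# autocorrelation exp(-d^2/(4*sigma^2)) with 1/e half-width L.
gaussian_kernel_1d <- function(sigma) {
  half <- max(1L, ceiling(3 * sigma))
  x <- (-half):half
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Correlated unit-mean multiplicative speckle field: exp of a low-pass
# filtered Gaussian field rescaled so that sd(S)/mean(S) == contrast
# exactly in expectation and S > 0 always.
speckle_field <- function(nrow, ncol, contrast, len_axial, len_lateral) {
  if (contrast == 0) return(matrix(1, nrow, ncol))
  g <- matrix(rnorm(nrow * ncol), nrow, ncol)
  ka <- gaussian_kernel_1d(len_axial / 2)
  kl <- gaussian_kernel_1d(len_lateral / 2)
  kern <- outer(ka, kl)
  g <- EBImage::filter2(g, kern, boundary = "circular")
  sg <- sqrt(log(1 + contrast^2))
  g <- (g - mean(g)) * (sg / sd(g))
  exp(g - sg^2 / 2)
}

# True (continuous) surface row per column for a config.
surface_profile <- function(cfg) {
  cols <- seq_len(cfg$image_width)
  cfg$surface_apex_row +
    cfg$surface_curvature * (cols - cfg$image_width / 2)^2
}

#' Generate one synthetic pearl B-scan
#'
#' Paints a bright, parabolically curved nacre band over a dark noisy
#' background. The band interior is `mean_intensity * exp(-depth_decay *
#' depth) * S(row, col)` where `S` is the class's correlated unit-mean
#' multiplicative speckle field; pixels outside the band are rectified
#' Gaussian noise `|N(0, background_noise_sigma)|`. Output is clipped to
#' 8-bit integers.
#'
#' @param cfg a [synth_config()].
#' @param label luster grade, one of `names(cfg$class_params)`.
#' @param seed optional integer seed; when given the image is a pure
#'   function of `(cfg, label, seed)`.
#' @return Integer matrix (`image_height` x `image_width`, gray levels
#'   0-255) with attributes `label`, `surface` (the true continuous surface
#'   row per column) and `band_mask` (logical matrix, TRUE inside the nacre
#'   band).
#' @export
generate_bscan <- function(cfg, label, seed = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  if (!label %in% names(cfg$class_params))
    stop("unknown class label: ", label, call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  p <- cfg$class_params[[label]]
  h <- cfg$image_height; w <- cfg$image_width
  surf <- surface_profile(cfg)

  # depth below the surface, per pixel (negative above the surface)
  depth <- outer(seq_len(h), surf, "-")
  band <- depth >= 0 & depth < cfg$nacre_thickness

  img <- matrix(0, h, w)
  if (cfg$background_noise_sigma > 0)
    img[!band] <- abs(rnorm(sum(!band), 0, cfg$background_noise_sigma))
  if (p$mean_intensity > 0 && any(band)) {
    s <- speckle_field(h, w, p$speckle_contrast,
                       p$correlation_length_axial,
                       p$correlation_length_lateral)
    signal <- p$mean_intensity * exp(-p$depth_decay * depth) * s
    img[band] <- signal[band]
  }
  img <- matrix(as.integer(pmin(255, pmax(0, round(img)))), h, w)
  structure(img, label = label, surface = surf, band_mask = band)
}

#' Generate a labeled synthetic dataset
#'
#' Produces `n_per_class` B-scans for each of the four grades. Per-image
#' seeds are drawn once from `seed`, so the whole dataset is bit-identical
#' across calls with the same `(cfg, n_per_class, seed)`.
#'
#' @param cfg a [synth_config()].
#' @param n_per_class images per grade (>= 1).
#' @param seed integer root seed.
#' @return A list of class `labeled_dataset` with elements `images` (list of
#'   B-scan matrices), `labels` (factor with levels A-D) and `seed`.
#' @export
generate_dataset <- function(cfg, n_per_class, seed = 1L) {
  if (n_per_class < 1) stop("n_per_class must be >= 1", call. = FALSE)
  labels <- rep(names(cfg$class_params), each = n_per_class)
  set.seed(seed)
  image_seeds <- sample.int(.Machine$integer.max, length(labels))
  images <- mapply(function(lab, s) generate_bscan(cfg, lab, seed = s),
                   labels, image_seeds, SIMPLIFY = FALSE)
  names(images) <- sprintf("%s_%03d", labels, seq_along(labels))
  structure(list(images = images,
                 labels = factor(labels, levels = names(cfg$class_params)),
                 seed = seed),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat("Synthetic OCT B-scan dataset:", length(x$images), "images\n")
  print(table(x$labels))
  invisible(x)
}

#' Write a dataset to disk as 8-bit grayscale PNGs plus a manifest CSV
#'
#' The manifest records filename, label, the root seed and the speckle
#' parameters used for each image's class.
#'
#' @param dataset a `labeled_dataset` from [generate_dataset()].
#' @param cfg the [synth_config()] used to generate it.
#' @param dir output directory (created if missing).
#' @return Invisibly, the manifest data frame.
#' @export
write_dataset <- function(dataset, cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(dataset$images), function(i) {
    lab <- as.character(dataset$labels[[i]])
    fn <- paste0(names(dataset$images)[i], ".png")
    write_bscan_png(dataset$images[[i]], file.path(dir, fn))
    p <- cfg$class_params[[lab]]
    data.frame(filename = fn, label = lab, seed = dataset$seed,
               mean_intensity = p$mean_intensity,
               speckle_contrast = p$speckle_contrast,
               correlation_length_axial = p$correlation_length_axial,
               correlation_length_lateral = p$correlation_length_lateral,
               depth_decay = p$depth_decay)
  })
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
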