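# Shared fixtures, all generated in code.

rand_roi <- function(n = 8, seed = 1) {
  set.seed(seed)
  matrix(runif(n * n) * 255, n, n)
}

# small, fast geometry for pipeline-level tests
small_cfg <- function(...) {
  synth_config(image_height = 256L, image_width = 256L,
               surface_apex_row = 60, surface_curvature = 0.0012,
               nacre_thickness = 150, background_noise_sigma = 4, ...)
}

# flat-surface, noise-free band image with a sharp top edge at `edge_row`
flat_band_image <- function(h = 200, w = 100, edge_row = 100, value = 200) {
  img <- matrix(0L, h, w)
  img[edge_row:h, ] <- value
  img
}
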