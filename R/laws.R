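#' Laws 1-D texture masks
#'
#' Level, edge, spot and ripple masks; the 2-D kernels are outer products
#' of two of them. The 3-tap masks are included for reference; the feature
#' block uses the 5-tap set.
#'
#' @return Named list of numeric vectors.
#' @export
laws_masks <- function() {
  list(L5 = c(1, 4, 6, 4, 1),
       E5 = c(-1, -2, 0, 2, 1),
       S5 = c(-1, 0, 2, 0, -1),
       R5 = c(1, -4, 6, -4, 1),
       L3 = c(1, 2, 1),
       E3 = c(-1, 0, 1),
       S3 = c(-1, 2, -1))
}

#' The 9 Laws mask combinations (L5L5 excluded)
#'
#' @return List of character pairs in fixed order.
#' @export
laws_combos <- function() {
  list(c("L5", "E5"), c("L5", "S5"), c("L5", "R5"),
       c("E5", "S5"), c("E5", "R5"), c("E5", "E5"),
       c("S5", "R5"), c("S5", "S5"), c("R5", "R5"))
}

#' Laws texture-energy block (18 values)
#'
#' The mean-subtracted ROI is filtered with each 2-D kernel (reflect
#' padding). For the mirrored asymmetric pairs (e.g. L5E5/E5L5) the
#' texture-energy map is the average of the two orders' absolute responses;
#' for symmetric combos it is the single absolute response. Each map's mean
#' and standard deviation are emitted.
#'
#' @param roi ROI matrix or `roi_patch`.
#' @param masks named list of 1-D masks, see [laws_masks()].
#' @param combos list of mask-name pairs, see [laws_combos()].
#' @return Named numeric vector: 9 energy means then 9 standard deviations.
#' @export
extract_laws <- function(roi, masks = laws_masks(), combos = laws_combos()) {
  x <- as_roi_matrix(roi)
  x <- x - mean(x)
  maps <- lapply(combos, function(cb) {
    k1 <- outer(masks[[cb[1]]], masks[[cb[2]]])
    m <- abs(conv2_reflect(x, k1))
    if (cb[1] != cb[2]) {
      m <- (m + abs(conv2_reflect(x, t(k1)))) / 2
    }
    m
  })
  nm <- sprintf("laws_%s%s", vapply(combos, `[`, "", 1),
                vapply(combos, `[`, "", 2))
  c(setNames(vapply(maps, mean, numeric(1)), paste0(nm, "_mean")),
    setNames(vapply(maps, sd, numeric(1)), paste0(nm, "_std")))
}
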