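#' Fractal dimension by differential box counting
#'
#' The gray surface over an `side x side` ROI is covered with boxes of
#' lateral size `s` and height `h = s * gray_range / side`; each `s x s`
#' block contributes `ceil(max/h) - ceil(min/h) + 1` boxes. The fractal
#' dimension is the slope of the least-squares fit of `log N(s)` against
#' `log(1/s)`. A constant ROI gives exactly 2; rough i.i.d. noise
#' approaches 3.
#'
#' @param roi ROI matrix or `roi_patch`.
#' @param box_sizes lateral box sizes; sizes that do not divide the ROI
#'   side are dropped.
#' @param gray_range gray-level span of the data (256 for 8-bit).
#' @return Scalar fractal dimension (named `fd`).
#' @export
extract_fd <- function(roi, box_sizes = c(2, 4, 8, 16, 32, 64),
                       gray_range = 256) {
  x <- as_roi_matrix(roi)
  side <- min(dim(x))
  s_ok <- box_sizes[box_sizes <= side / 2 &
                    nrow(x) %% box_sizes == 0 & ncol(x) %% box_sizes == 0]
  if (length(s_ok) < 2)
    stop("need at least two valid box sizes for the ROI dimensions",
         call. = FALSE)
  n_boxes <- vapply(s_ok, function(s) {
    hs <- s * gray_range / side
    mx <- block_reduce(x, s, max)
    mn <- block_reduce(x, s, min)
    sum(ceiling(mx / hs) - ceiling(mn / hs) + 1)
  }, numeric(1))
  fit <- lm.fit(cbind(1, log(1 / s_ok)), log(n_boxes))
  c(fd = unname(fit$coefficients[2]))
}

# Reduce non-overlapping s x s blocks of x with FUN (max/min).
block_reduce <- function(x, s, FUN) {
  h <- nrow(x); w <- ncol(x)
  a <- array(x, c(s, h %/% s, w))
  m <- apply(a, c(2, 3), FUN)              # (h/s) x w
  a2 <- array(t(m), c(s, w %/% s, h %/% s))
  t(apply(a2, c(2, 3), FUN))               # (h/s) x (w/s)
}

#' Center-symmetric auto-correlation block (12 values)
#'
#' For every interior pixel the 3x3 neighborhood provides four
#' center-symmetric pixel pairs (NW/SE, N/S, NE/SW, W/E) and the mean `mu`
#' of the eight neighbors. Six indicators are computed per neighborhood:
#' covariance SCOV, local variance VAR, between-pair variance BVAR,
#' within-pair variance WVAR, the variance ratio SVR = BVAR/(WVAR + 1e-12)
#' and the normalized covariance SAC = SCOV/VAR (0 where VAR = 0, so SAC
#' lies in \[-1, 1\]). SAC and SVR are invariant under linear gray maps
#' `a*x + b` (a > 0). The block holds the mean and standard deviation of
#' each indicator over all neighborhoods.
#'
#' @param roi ROI matrix or `roi_patch`, at least 3x3.
#' @return Named numeric vector: 6 indicator means then 6 standard
#'   deviations, order scov, var, bvar, wvar, svr, sac.
#' @export
extract_csac <- function(roi) {
  x <- as_roi_matrix(roi)
  h <- nrow(x); w <- ncol(x)
  if (h < 3 || w < 3) stop("CSAC needs an ROI of at least 3x3", call. = FALSE)
  nb <- function(dr, dc) x[(2 + dr):(h - 1 + dr), (2 + dc):(w - 1 + dc),
                           drop = FALSE]
  nw <- nb(-1, -1); nn <- nb(-1, 0); ne <- nb(-1, 1); ww <- nb(0, -1)
  ee <- nb(0, 1); sw <- nb(1, -1); ss <- nb(1, 0); se <- nb(1, 1)
  mu <- (nw + nn + ne + ww + ee + sw + ss + se) / 8

  scov <- ((nw - mu) * (se - mu) + (nn - mu) * (ss - mu) +
           (ne - mu) * (sw - mu) + (ww - mu) * (ee - mu)) / 4
  v <- ((nw - mu)^2 + (nn - mu)^2 + (ne - mu)^2 + (ww - mu)^2 +
        (ee - mu)^2 + (sw - mu)^2 + (ss - mu)^2 + (se - mu)^2) / 8
  m1 <- (nw + se) / 2; m2 <- (nn + ss) / 2; m3 <- (ne + sw) / 2
  m4 <- (ww + ee) / 2
  wvar <- ((nw - m1)^2 + (nn - m2)^2 + (ne - m3)^2 + (ww - m4)^2) / 4
  bvar <- ((m1 - mu)^2 + (m2 - mu)^2 + (m3 - mu)^2 + (m4 - mu)^2) / 4
  svr <- bvar / (wvar + 1e-12)
  sac <- ifelse(v > 0, scov / v, 0)

  ind <- list(scov = scov, var = v, bvar = bvar, wvar = wvar,
              svr = svr, sac = sac)
  c(setNames(vapply(ind, mean, numeric(1)),
             sprintf("csac_%s_mean", names(ind))),
    setNames(vapply(ind, sd, numeric(1)),
             sprintf("csac_%s_std", names(ind))))
}

#' Names of the 237 texture features, in feature-vector order
#'
#' Family order and block sizes: FD\[1\], GLCM\[40+40\], LBP\[14+14\],
#' Gabor\[40+40\], HOG\[9+9\], LAWS\[9+9\], CSAC\[6+6\].
#'
#' @param glcm,lbp,gabor configurations (defaults give the standard
#'   layout).
#' @param hog_bins HOG orientation bins.
#' @param laws list of mask-name pairs.
#' @return Character vector of length 237.
#' @export
feature_names <- function(glcm = glcm_config(), lbp = lbp_pairs(),
                          gabor = gabor_config(), hog_bins = 9L,
                          laws = laws_combos()) {
  g <- as.vector(t(outer(glcm$statistics, sprintf("d%02d", glcm$distances),
                         function(s, d) paste0("glcm_", s, "_", d))))
  l <- sprintf("lbp_p%d_r%d", lbp$P, lbp$R)
  gb <- as.vector(t(outer(gabor$wavelengths, gabor$orientations,
                          function(w, o) sprintf("gabor_w%02d_o%03d", w, o))))
  hg <- sprintf("hog_bin%d", seq_len(hog_bins))
  lw <- sprintf("laws_%s%s", vapply(laws, `[`, "", 1),
                vapply(laws, `[`, "", 2))
  cs <- paste0("csac_", c("scov", "var", "bvar", "wvar", "svr", "sac"))
  ms <- function(x) c(paste0(x, "_mean"), paste0(x, "_std"))
  c("fd", ms(g), ms(l), ms(gb), ms(hg), ms(lw), ms(cs))
}

#' Descriptor family of each feature
#'
#' @param names feature names as produced by [feature_names()].
#' @return Factor with levels FD, GLCM, LBP, Gabor, HOG, LAWS, CSAC.
#' @export
feature_families <- function(names = feature_names()) {
  prefix <- sub("_.*$", "", names)
  map <- c(fd = "FD", glcm = "GLCM", lbp = "LBP", gabor = "Gabor",
           hog = "HOG", laws = "LAWS", csac = "CSAC")
  factor(unname(map[prefix]), levels = unname(map))
}

#' Assemble the 237-element texture feature vector
#'
#' Runs all seven descriptor families on a 128x128 ROI and concatenates
#' their blocks in the fixed family order FD, GLCM, LBP, Gabor, HOG, LAWS,
#' CSAC. A failure in any family is re-signalled with the family named.
#'
#' @param roi a `roi_patch` or 128x128 matrix of gray levels 0-255.
#' @param glcm,lbp,gabor descriptor configurations.
#' @return Named numeric vector of length 237.
#' @export
assemble_features <- function(roi, glcm = glcm_config(), lbp = lbp_pairs(),
                              gabor = gabor_config()) {
  x <- as_roi_matrix(roi)
  run <- function(family, expr) {
    tryCatch(expr, error = function(e)
      stop(family, " feature extraction failed: ", conditionMessage(e),
           call. = FALSE))
  }
  out <- c(run("FD", extract_fd(x)),
           run("GLCM", extract_glcm(x, glcm)),
           run("LBP", extract_lbp(x, lbp)),
           run("Gabor", extract_gabor(x, gabor)),
           run("HOG", extract_hog(x)),
           run("LAWS", extract_laws(x)),
           run("CSAC", extract_csac(x)))
  stopifnot(length(out) == 237L, all(is.finite(out)))
  out
}

#' Feature table from a labeled dataset of B-scans
#'
#' Locates the ROI in every image and extracts the 237 texture features.
#'
#' @param dataset a `labeled_dataset` (or list with `images`, `labels`).
#' @param ... passed to [locate_roi()].
#' @return A `feature_table`: list with `matrix` (n x 237), `labels`
#'   (factor) and `feature_names`.
#' @export
extract_dataset_features <- function(dataset, ...) {
  feats <- t(vapply(dataset$images,
                    function(img) assemble_features(locate_roi(img, ...)$roi),
                    numeric(237L)))
  feature_table(feats, dataset$labels)
}
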