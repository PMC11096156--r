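# Independent brute-force oracles for the texture descriptors: explicit
# double loops, no shared code with the implementations in R/.

oracle_glcm_matrix <- function(x, levels, dr, dc) {
  q <- floor(x * levels / 256)
  q[q > levels - 1] <- levels - 1
  q[q < 0] <- 0
  P <- matrix(0, levels, levels)
  h <- nrow(x); w <- ncol(x)
  for (r in 1:h) for (cc in 1:w) {
    r2 <- r + dr; c2 <- cc + dc
    if (r2 >= 1 && r2 <= h && c2 >= 1 && c2 <= w) {
      i <- q[r, cc] + 1; j <- q[r2, c2] + 1
      P[i, j] <- P[i, j] + 1
      P[j, i] <- P[j, i] + 1   # symmetric matrix
    }
  }
  P / sum(P)
}

oracle_glcm_stat <- function(P, stat) {
  L <- nrow(P)
  if (stat == "entropy") {
    v <- 0
    for (i in 1:L) for (j in 1:L)
      if (P[i, j] > 0) v <- v - P[i, j] * log2(P[i, j])
    return(v)
  }
  if (stat == "energy") {
    v <- 0
    for (i in 1:L) for (j in 1:L) v <- v + P[i, j]^2
    return(v)
  }
  if (stat == "contrast") {
    v <- 0
    for (i in 1:L) for (j in 1:L) v <- v + (i - j)^2 * P[i, j]
    return(v)
  }
  if (stat == "correlation") {
    mx <- my <- 0
    for (i in 1:L) for (j in 1:L) {
      mx <- mx + (i - 1) * P[i, j]
      my <- my + (j - 1) * P[i, j]
    }
    sx <- sy <- 0
    for (i in 1:L) for (j in 1:L) {
      sx <- sx + (i - 1 - mx)^2 * P[i, j]
      sy <- sy + (j - 1 - my)^2 * P[i, j]
    }
    if (sx == 0 || sy == 0) return(0)
    v <- 0
    for (i in 1:L) for (j in 1:L)
      v <- v + (i - 1 - mx) * (j - 1 - my) * P[i, j]
    return(v / sqrt(sx * sy))
  }
  stop("unknown stat")
}

# direction convention mirrors the descriptor definition (row 1 = top)
oracle_glcm_offset <- function(angle, d) {
  if (angle == 0) c(0, d)
  else if (angle == 45) c(-d, d)
  else if (angle == 90) c(-d, 0)
  else c(-d, -d)
}

oracle_glcm_features <- function(x, levels, distances) {
  angles <- c(0, 45, 90, 135)
  means <- c(); stds <- c()
  for (stat in c("entropy", "energy", "correlation", "contrast")) {
    for (d in distances) {
      vals <- sapply(angles, function(a) {
        off <- oracle_glcm_offset(a, d)
        oracle_glcm_stat(oracle_glcm_matrix(x, levels, off[1], off[2]), stat)
      })
      means <- c(means, mean(vals))
      stds <- c(stds, sd(vals))
    }
  }
  c(means, stds)
}

oracle_lbp_code <- function(x, P, R) {
  m <- ceiling(R)
  h <- nrow(x); w <- ncol(x)
  out <- matrix(NA_real_, h - 2 * m, w - 2 * m)
  for (r in (m + 1):(h - m)) for (cc in (m + 1):(w - m)) {
    code <- 0
    for (k in 0:(P - 1)) {
      a <- 2 * pi * k / P
      dr <- -R * sin(a); dc <- R * cos(a)
      if (abs(dr - round(dr)) < 1e-6) dr <- round(dr)
      if (abs(dc - round(dc)) < 1e-6) dc <- round(dc)
      rr <- r + dr; cx <- cc + dc
      r0 <- floor(rr); c0 <- floor(cx)
      fr <- rr - r0; fc <- cx - c0
      v <- (1 - fr) * (1 - fc) * x[r0, c0]
      if (fc > 0) v <- v + (1 - fr) * fc * x[r0, c0 + 1]
      if (fr > 0) v <- v + fr * (1 - fc) * x[r0 + 1, c0]
      if (fr > 0 && fc > 0) v <- v + fr * fc * x[r0 + 1, c0 + 1]
      if (v >= x[r, cc] - 1e-7) code <- code + 2^k
    }
    out[r - m, cc - m] <- code
  }
  out
}

# single 3x3 neighborhood -> the six CSAC indicators
oracle_csac_one <- function(nb) {
  nw <- nb[1, 1]; nn <- nb[1, 2]; ne <- nb[1, 3]
  ww <- nb[2, 1]; ee <- nb[2, 3]
  sw <- nb[3, 1]; ss <- nb[3, 2]; se <- nb[3, 3]
  xs <- c(nw, nn, ne, ww, ee, sw, ss, se)
  mu <- mean(xs)
  p1 <- c(nw, nn, ne, ww); p2 <- c(se, ss, sw, ee)
  scov <- mean((p1 - mu) * (p2 - mu))
  v <- mean((xs - mu)^2)
  mi <- (p1 + p2) / 2
  wvar <- mean((p1 - mi)^2)
  bvar <- mean((mi - mu)^2)
  c(scov = scov, var = v, bvar = bvar, wvar = wvar,
    svr = bvar / (wvar + 1e-12), sac = if (v > 0) scov / v else 0)
}

oracle_csac_features <- function(x) {
  h <- nrow(x); w <- ncol(x)
  vals <- matrix(NA_real_, (h - 2) * (w - 2), 6)
  i <- 0
  for (r in 2:(h - 1)) for (cc in 2:(w - 1)) {
    i <- i + 1
    vals[i, ] <- oracle_csac_one(x[(r - 1):(r + 1), (cc - 1):(cc + 1)])
  }
  c(colMeans(vals), apply(vals, 2, sd))
}

# reflect (mirror-with-edge) index used by the reflect-padded filtering
oracle_reflect <- function(i, n) {
  if (i < 1) 1 - i else if (i > n) 2 * n - i + 1 else i
}

oracle_conv_reflect <- function(x, kern) {
  h <- nrow(x); w <- ncol(x)
  kh <- nrow(kern); kw <- ncol(kern)
  ch <- (kh + 1) %/% 2; cw <- (kw + 1) %/% 2
  out <- matrix(0, h, w)
  for (r in 1:h) for (cc in 1:w) {
    acc <- 0
    for (a in 1:kh) for (b in 1:kw) {
      rr <- oracle_reflect(r + a - ch, h)
      cx <- oracle_reflect(cc + b - cw, w)
      acc <- acc + kern[a, b] * x[rr, cx]
    }
    out[r, cc] <- acc
  }
  out
}

oracle_laws_features <- function(x) {
  masks <- list(L5 = c(1, 4, 6, 4, 1), E5 = c(-1, -2, 0, 2, 1),
                S5 = c(-1, 0, 2, 0, -1), R5 = c(1, -4, 6, -4, 1))
  combos <- list(c("L5", "E5"), c("L5", "S5"), c("L5", "R5"),
                 c("E5", "S5"), c("E5", "R5"), c("E5", "E5"),
                 c("S5", "R5"), c("S5", "S5"), c("R5", "R5"))
  xm <- x - mean(x)
  maps <- lapply(combos, function(cb) {
    k <- outer(masks[[cb[1]]], masks[[cb[2]]])
    m <- abs(oracle_conv_reflect(xm, k))
    if (cb[1] != cb[2])
      m <- (m + abs(oracle_conv_reflect(xm, t(k)))) / 2
    m
  })
  c(sapply(maps, mean), sapply(maps, sd))
}

oracle_fd <- function(x, box_sizes, gray_range = 256) {
  side <- nrow(x)
  ns <- c()
  for (s in box_sizes) {
    hs <- s * gray_range / side
    total <- 0
    for (br in seq(1, side, by = s)) for (bc in seq(1, ncol(x), by = s)) {
      blk <- x[br:(br + s - 1), bc:(bc + s - 1)]
      total <- total + ceiling(max(blk) / hs) - ceiling(min(blk) / hs) + 1
    }
    ns <- c(ns, total)
  }
  lx <- log(1 / box_sizes); ly <- log(ns)
  sum((lx - mean(lx)) * (ly - mean(ly))) / sum((lx - mean(lx))^2)
}

oracle_hog_cells <- function(x, cell = 4, bins = 9) {
  h <- nrow(x); w <- ncol(x)
  H <- matrix(0, (h / cell) * (w / cell), bins)
  for (r in 1:h) for (cc in 1:w) {
    gx <- (x[r, min(cc + 1, w)] - x[r, max(cc - 1, 1)]) / 2
    gy <- (x[min(r + 1, h), cc] - x[max(r - 1, 1), cc]) / 2
    mag <- sqrt(gx^2 + gy^2)
    th <- (atan2(gy, gx) * 180 / pi) %% 180
    b <- min(floor(th / (180 / bins)) + 1, bins)
    cell_id <- ((r - 1) %/% cell) * (w %/% cell) + (cc - 1) %/% cell + 1
    H[cell_id, b] <- H[cell_id, b] + mag
  }
  H
}
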