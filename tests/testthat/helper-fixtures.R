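# shared fixture builders; everything is generated in code at test time

# gray RasterImage from a matrix of 8-bit intensities
grayImage <- function(m) RasterImage(as.matrix(m), 8L)

# RGB RasterImage from three matrices
rgbImage <- function(r, g, b) {
  a <- array(0, c(nrow(r), ncol(r), 3))
  a[, , 1] <- r; a[, , 2] <- g; a[, , 3] <- b
  RasterImage(a, 8L)
}

# flat-color RGB image
flatRgb <- function(h, w, col) rgbImage(matrix(col[1], h, w),
                                        matrix(col[2], h, w),
                                        matrix(col[3], h, w))

# seeded random 8-bit gray matrix
randGray <- function(h, w, seed = 1, levels = 256) {
  set.seed(seed)
  matrix(sample(0:(levels - 1), h * w, replace = TRUE), h, w)
}

# light background with dark disks at the given centers/radii (gray matrix)
diskImage <- function(h, w, centers, radius, bg = 220, fg = 40) {
  m <- matrix(bg, h, w)
  rows <- matrix(seq_len(h), h, w); cols <- t(matrix(seq_len(w), w, h))
  for (i in seq_len(nrow(centers))) {
    d2 <- (rows - centers[i, 1])^2 + (cols - centers[i, 2])^2
    m[d2 <= radius^2] <- fg
  }
  m
}

# brute-force co-occurrence feature oracle: explicit pair enumeration and
# double-loop statistics, independent of the vectorized implementation
oracleGlcmFeatures <- function(gray, levels, angle, symmetric = TRUE,
                               homogeneityForm = "printed") {
  offs <- list(`0` = c(0, 1), `45` = c(-1, 1), `90` = c(-1, 0),
               `135` = c(-1, -1))[[as.character(angle)]]
  H <- nrow(gray); W <- ncol(gray)
  cnt <- matrix(0, levels, levels)
  for (r in seq_len(H)) for (c in seq_len(W)) {
    r2 <- r + offs[1]; c2 <- c + offs[2]
    if (r2 >= 1 && r2 <= H && c2 >= 1 && c2 <= W) {
      i <- gray[r, c] + 1; j <- gray[r2, c2] + 1
      cnt[i, j] <- cnt[i, j] + 1
      if (symmetric) cnt[j, i] <- cnt[j, i] + 1
    }
  }
  p <- cnt / sum(cnt)
  px <- rowSums(p); py <- colSums(p)
  lv <- 0:(levels - 1)
  mx <- sum(lv * px); my <- sum(lv * py)
  sx <- sqrt(sum((lv - mx)^2 * px)); sy <- sqrt(sum((lv - my)^2 * py))
  f <- c(contrast = 0, homogeneity = 0, correlation = 0, energy = 0,
         dissimilarity = 0, entropy = 0)
  for (i in 0:(levels - 1)) for (j in 0:(levels - 1)) {
    pij <- p[i + 1, j + 1]
    f["contrast"] <- f["contrast"] + (i - j)^2 * pij
    den <- if (homogeneityForm == "printed") 1 + (i + j)^2 else 1 + (i - j)^2
    f["homogeneity"] <- f["homogeneity"] + pij / den
    f["energy"] <- f["energy"] + pij^2
    f["dissimilarity"] <- f["dissimilarity"] + abs(i - j) * pij
    if (sx > 0 && sy > 0)
      f["correlation"] <- f["correlation"] + pij * (i - mx) * (j - my) / (sx * sy)
    if (pij > 0) f["entropy"] <- f["entropy"] - pij * log2(pij)
  }
  f
}

# brute-force run enumeration for one direction: walks each scan line
# pixel by pixel
oracleRuns <- function(gray, angle) {
  H <- nrow(gray); W <- ncol(gray)
  starts <- switch(as.character(angle),
    `0`   = lapply(seq_len(H), function(r) cbind(r, seq_len(W))),
    `90`  = lapply(seq_len(W), function(c) cbind(seq_len(H), c)),
    `45`  = lapply(seq(2, H + W), function(s) {
      r <- seq(min(s - 1, H), max(1, s - W)); cbind(r, s - r) }),
    `135` = lapply(seq(1 - W, H - 1), function(d) {
      r <- seq(max(1, 1 + d), min(H, W + d)); cbind(r, r - d) }))
  runs <- list()
  for (ln in starts) {
    vals <- gray[ln]
    cur <- vals[1]; len <- 1
    if (length(vals) > 1) for (i in 2:length(vals)) {
      if (vals[i] == cur) len <- len + 1
      else { runs[[length(runs) + 1]] <- c(cur, len); cur <- vals[i]; len <- 1 }
    }
    runs[[length(runs) + 1]] <- c(cur, len)
  }
  do.call(rbind, runs)   # columns: level, length
}

oracleGlrlmFeatures <- function(gray, nGray, angle) {
  runs <- oracleRuns(gray, angle)
  total <- nrow(runs)
  muG <- mean(gray + 1)
  muR <- mean(runs[, 2])
  f <- c(SRE = 0, LRE = 0, GLN = 0, RLN = 0)
  for (k in seq_len(total)) {
    i <- runs[k, 1] + 1; j <- runs[k, 2]; p <- 1 / total
    f["SRE"] <- f["SRE"] + p / (1 + (i + j))
    f["LRE"] <- f["LRE"] + p / (1 + abs(i - j))
    f["GLN"] <- f["GLN"] + p * (i - muG)^2
    f["RLN"] <- f["RLN"] + p * (j - muR)^2
  }
  f
}

# independent per-pixel circular sampler (scalar code) for LBP-geometry
# oracles
oracleCircularSamples <- function(gray, r, c, P, R) {
  vapply(seq_len(P) - 1, function(p) {
    ang <- 2 * pi * p / P
    dc <- R * cos(ang); dr <- -R * sin(ang)
    if (abs(dc - round(dc)) < 1e-9) dc <- round(dc)
    if (abs(dr - round(dr)) < 1e-9) dr <- round(dr)
    rr <- r + dr; cc <- c + dc
    r0 <- floor(rr); c0 <- floor(cc)
    fr <- rr - r0; fc <- cc - c0
    r1 <- min(r0 + 1, nrow(gray)); c1 <- min(c0 + 1, ncol(gray))
    gray[r0, c0] * (1 - fr) * (1 - fc) + gray[r1, c0] * fr * (1 - fc) +
      gray[r0, c1] * (1 - fr) * fc + gray[r1, c1] * fr * fc
  }, numeric(1))
}

# mode with first-vote tie-break, by explicit counting
oracleMajority <- function(v) {
  tab <- sapply(unique(v), function(u) sum(v == u))
  winners <- names(tab)[tab == max(tab)]
  if (length(winners) == 1) winners else v[1]
}

# AUC by explicit concordant/tied pair counting
oracleAuc <- function(scores, positive) {
  pos <- scores[positive]; neg <- scores[!positive]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(pos) * length(neg))
}
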