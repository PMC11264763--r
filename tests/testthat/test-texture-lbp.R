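test_that("LBP code construction follows the s(x>=0) threshold convention", {
  cst <- matrix(100, 8, 8)
  m <- lbpMap(cst, 8L, 1, "basic")
  expect_true(all(m@codes == 255L))          # s(0) = 1 on every neighbor

  mr <- lbpMap(cst, 8L, 1, "riu2")
  expect_true(all(mr@codes == 8L))           # uniform all-ones class

  # basic codes against the independent per-pixel sampler
  g <- randGray(10, 10, 21)
  mb <- lbpMap(g, 8L, 1, "basic")
  for (pt in list(c(3, 3), c(5, 8), c(9, 2))) {
    nb <- oracleCircularSamples(g, pt[1], pt[2], 8L, 1)
    code <- sum((nb >= g[pt[1], pt[2]]) * 2^(0:7))
    expect_equal(mb@codes[pt[1] - 1, pt[2] - 1], code)
  }
  expect_error(lbpMap(matrix(1, 2, 2), 8L, 1), "neighborhood")
})

test_that("worked binary-string conversion yields its decimal code", {
  expect_identical(lbpStringToDecimal("11001001"), 201)
  expect_identical(lbpStringToDecimal("00000000"), 0)
  expect_identical(lbpStringToDecimal("11111111"), 255)
})

test_that("riu2 histograms are invariant to right-angle rotation and flips", {
  g <- randGray(16, 16, 22)
  img <- grayImage(g)
  hist0 <- tabulate(lbpMap(g, 8L, 1, "riu2")@codes + 1L, 10L)
  for (k in 1:3) {
    gr <- pixels(augmentImage(img, "rotate", k = k))
    expect_equal(tabulate(lbpMap(gr, 8L, 1, "riu2")@codes + 1L, 10L), hist0)
  }
  for (ax in c("h", "v")) {
    gf <- pixels(augmentImage(img, "flip", axis = ax))
    expect_equal(tabulate(lbpMap(gf, 8L, 1, "riu2")@codes + 1L, 10L), hist0)
  }
})

test_that("multi-resolution LBP histograms are normalized blocks", {
  g <- randGray(24, 24, 23)
  v <- lbpHistogramFeatures(g)
  expect_length(v, 10 + 18 + 26)
  expect_equal(sum(v[grepl("^p8r1", names(v))]), 1)
  expect_equal(sum(v[grepl("^p16r2", names(v))]), 1)
  expect_equal(sum(v[grepl("^p24r3", names(v))]), 1)

  flat <- lbpHistogramFeatures(matrix(7, 24, 24), list(c(8, 1)))
  expect_equal(sum(flat > 0), 1L)            # one-hot on a constant image
})

test_that("heterogeneity maps match Eq-style hand values and a brute oracle", {
  cst <- matrix(42, 8, 8)
  h <- heterogeneityMaps(cst, 8L, 1)
  expect_true(all(h@varianceMap == 0))
  expect_true(all(h@homogeneityMap == 1))

  # half-0 half-255 neighborhood: V = (255/2)^2
  g <- matrix(0, 5, 5); g[, 4:5] <- 255
  # center at (3,3): axial+diagonal samples straddle the step edge
  hv <- heterogeneityMaps(g, 4L, 1)          # 4 axial neighbors, exact
  # neighborhood of (3,3) at P=4: {g(3,4), g(2,3), g(3,2), g(4,3)} = {255,0,0,0}
  expect_equal(hv@varianceMap[2, 2], mean((c(255, 0, 0, 0) - 63.75)^2))

  gg <- randGray(16, 16, 24)
  got <- heterogeneityMaps(gg, 8L, 1)
  for (r in 2:15) for (c in c(2, 9, 15)) {
    nb <- oracleCircularSamples(gg, r, c, 8L, 1)
    expect_equal(got@varianceMap[r - 1, c - 1], mean((nb - mean(nb))^2),
                 tolerance = 1e-12)
    expect_equal(got@homogeneityMap[r - 1, c - 1],
                 1 - sqrt(sum((nb - median(nb))^2)) / 8, tolerance = 1e-12)
  }
})

test_that("heterogeneity-weighted histograms accumulate per-pixel weights", {
  cst <- matrix(9, 10, 10)
  m <- lbpMap(cst, 8L, 1, "riu2"); h <- heterogeneityMaps(cst, 8L, 1)
  wv <- heterogeneityWeightedLbp(m, h, "variance")
  expect_true(all(wv == 0))                  # zero total weight documented

  g <- randGray(16, 16, 25)
  m2 <- lbpMap(g, 8L, 1, "riu2"); h2 <- heterogeneityMaps(g, 8L, 1)
  got <- heterogeneityWeightedLbp(m2, h2, "dissimilarity")
  # brute-force accumulation loop
  acc <- numeric(10)
  w <- 1 - h2@homogeneityMap
  for (i in seq_along(m2@codes))
    acc[m2@codes[i] + 1] <- acc[m2@codes[i] + 1] + w[i]
  expect_equal(unname(got), acc / sum(acc), tolerance = 1e-12)

  # uniform positive weights reduce to the plain normalized histogram
  h3 <- h2; h3@varianceMap[] <- 3.7
  expect_equal(unname(heterogeneityWeightedLbp(m2, h3, "variance")),
               tabulate(m2@codes + 1L, 10L) / length(m2@codes))
})

test_that("image pyramid halves sizes and preserves constants", {
  g <- randGray(64, 64, 26)
  pyr <- imagePyramid(g, 3L)
  expect_equal(vapply(pyr, nrow, integer(1)), c(64L, 32L, 16L))
  expect_identical(imagePyramid(g, 1L)[[1]], g)
  cpy <- imagePyramid(matrix(50, 64, 64), 3L)
  for (lv in cpy) expect_true(max(abs(lv - 50)) < 1e-6)
  expect_error(imagePyramid(randGray(16, 16, 1), 3L), "levels")
})

test_that("LBGLCM equals the explicit operator chain and separates classes", {
  cst <- matrix(5, 12, 12)
  f <- lbglcmFeatures(cst)
  expect_equal(unname(f["contrast"]), 0)
  expect_equal(unname(f["energy"]), 1)

  g <- randGray(20, 20, 27)
  chain <- {
    map <- lbpMap(g, 8L, 1, "basic")
    q <- matrix(as.integer(pmin(floor(map@codes * 64 / 256), 63L)),
                nrow(map@codes), ncol(map@codes))
    glcmFeatures(computeGlcm(q, 64L))
  }
  expect_equal(lbglcmFeatures(g), chain, tolerance = 1e-12)

  specs <- list(
    sparse = list(density = 8,  radius = 3.4, radiusSd = 0.4,
                  tint = c(220, 190, 215), noiseSd = 5),
    dense  = list(density = 60, radius = 2.6, radiusSd = 0.4,
                  tint = c(220, 190, 215), noiseSd = 5))   # same tint: texture only
  d <- generateTextureDataset(20, classes = specs, imageSize = 64, seed = 6)
  contrast <- vapply(images(d), function(im)
    lbglcmFeatures(0.299 * pixels(im)[, , 1] + 0.587 * pixels(im)[, , 2] +
                   0.114 * pixels(im)[, , 3])["contrast"], numeric(1))
  m <- tapply(contrast, imageLabels(d), mean)
  s <- tapply(contrast, imageLabels(d), stats::sd)
  sep <- abs(diff(m)) / sqrt(sum(s^2 / 20))
  expect_gt(sep, 3)      # class means separated well beyond sampling noise
})

test_that("the multi-scale descriptor concatenates per-level blocks", {
  g <- randGray(64, 64, 28)
  v <- multiscaleLbglcm(g, nLevels = 3L)
  expect_length(v, 18L)
  expect_true(all(grepl("^l[012]\\.", names(v))))

  v1 <- multiscaleLbglcm(g, nLevels = 1L, levels = 64L)
  expect_equal(unname(v1), unname(lbglcmFeatures(g, levels = 64L)),
               tolerance = 1e-12)

  # frozen min-max stats reproduce the training-time transform
  st <- list(min = v - 1, max = v + 1)
  vn <- multiscaleLbglcm(g, nLevels = 3L, stats = st)
  expect_equal(unname(vn), rep(0.5, 18), tolerance = 1e-12)

  # scale consistency: level-1 block of an image tracks level-0 of its
  # downsample across fixture images (same quantization at both scales)
  d <- generateTextureDataset(10, imageSize = 64, seed = 8)
  lev1 <- t(vapply(images(d), function(im) {
    g <- 0.299 * pixels(im)[, , 1] + 0.587 * pixels(im)[, , 2] +
      0.114 * pixels(im)[, , 3]
    multiscaleLbglcm(g, nLevels = 2L, levels = c(64L, 64L))[7:12]
  }, numeric(6)))
  lev0 <- t(vapply(images(d), function(im) {
    g <- 0.299 * pixels(im)[, , 1] + 0.587 * pixels(im)[, , 2] +
      0.114 * pixels(im)[, , 3]
    down <- imagePyramid(g, 2L)[[2]]
    multiscaleLbglcm(down, nLevels = 1L, levels = 64L)
  }, numeric(6)))
  expect_equal(unname(lev1), unname(lev0), tolerance = 1e-10)
})
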