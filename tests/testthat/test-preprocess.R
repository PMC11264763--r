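test_that("log-normalization follows the scaled log(1+I) law", {
  z <- grayImage(matrix(0, 4, 4))
  expect_equal(pixels(logNormalize(z)), pixels(z))          # Imax = 0 case

  bin <- grayImage(matrix(c(0, 255), 4, 4))
  expect_equal(sort(unique(as.vector(pixels(logNormalize(bin))))), c(0, 255))

  m <- matrix(c(100, 255, 0, 30), 2, 2)
  out <- pixels(logNormalize(grayImage(m)))
  expect_equal(out[1, 1], round(255 * log(101) / log(256)))
  expect_equal(out[1, 1], 212)
  expect_equal(out[2, 1], 255)
  expect_equal(out[1, 2], 0)

  # monotone non-decreasing per channel
  g <- grayImage(randGray(12, 12, 4))
  o <- pixels(logNormalize(g))
  ord <- order(as.vector(pixels(g)))
  expect_true(all(diff(o[ord]) >= 0))
})

test_that("CLAHE keeps constants, range and approximates global equalization", {
  flat <- grayImage(matrix(120, 32, 32))
  out1 <- applyClahe(flat, grid = c(2, 2))
  expect_true(max(pixels(out1)) == min(pixels(out1)))       # constant in, constant out
  expect_equal(pixels(applyClahe(out1, grid = c(2, 2))), pixels(out1))  # idempotent

  img <- grayImage(randGray(64, 64, 5))
  out <- applyClahe(img, grid = c(8, 8), clipLimit = 4)
  expect_true(all(pixels(out) >= 0 & pixels(out) <= 255))
  expect_identical(dim(pixels(out)), dim(pixels(img)))

  # huge clip limit ~ (tiled) histogram equalization: compare the center
  # region of a smooth gradient against a rank/ecdf equalization oracle
  set.seed(9)
  m <- matrix(sample(0:255, 64 * 64, replace = TRUE), 64, 64)
  ce <- pixels(applyClahe(grayImage(m), grid = c(2, 2), clipLimit = 1e6))
  oracle <- matrix(round(255 * (rank(m) - 1) / (length(m) - 1)), 64, 64)
  expect_gt(cor(as.vector(ce), as.vector(oracle)), 0.99)

  expect_error(applyClahe(grayImage(matrix(1, 8, 8)), grid = c(8, 8)),
               "smaller")
})

test_that("tiling covers the divisible area in row-major order", {
  img <- grayImage(randGray(64, 64, 6))
  tiles <- tileImage(img, 32L, parentId = "x")
  expect_length(tiles, 4L)
  pos <- t(vapply(tiles, function(t) c(t@gridRow, t@gridCol), integer(2)))
  expect_equal(pos, rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1)))
  expect_equal(pixels(tiles[[2]]@image), pixels(img)[1:32, 33:64])

  # remainder discarded: 70 = 2*32 + 6
  t2 <- tileImage(grayImage(randGray(70, 70, 7)), 32L)
  expect_length(t2, 4L)

  # exact single tile is the identity
  t3 <- tileImage(img, 64L)
  expect_length(t3, 1L)
  expect_equal(pixels(t3[[1]]@image), pixels(img))

  expect_error(tileImage(grayImage(randGray(16, 16, 8)), 32L), "pad")
  t4 <- tileImage(grayImage(randGray(16, 16, 8)), 32L, pad = TRUE)
  expect_identical(dim(pixels(t4[[1]]@image)), c(32L, 32L))
})

test_that("watershed nuclei counting matches constructed ground truth", {
  expect_identical(nucleiDensity(grayImage(matrix(128, 64, 64))), 0L)

  # 12 well-separated dark disks are counted exactly
  centers <- as.matrix(expand.grid(r = c(10, 26, 42, 58), c = c(12, 32, 52)))
  img <- grayImage(diskImage(68, 64, centers, radius = 4))
  expect_equal(nucleiDensity(img), 12L)

  # two overlapping disks with distinct distance peaks are split
  two <- grayImage(diskImage(40, 40, rbind(c(18, 16), c(18, 24)), radius = 5))
  expect_equal(nucleiDensity(two), 2L)
})

test_that("ROI selection is a deterministic top-n with grid-order ties", {
  img <- grayImage(randGray(64, 64, 9))
  tiles <- tileImage(img, 32L)
  dens <- c(3, 9, 1, 9)
  rs <- selectRois(tiles, topN = 2L, densities = dens)
  expect_equal(rs@densities, c(9, 9))
  pos <- t(vapply(rs@rois, function(t) c(t@gridRow, t@gridCol), integer(2)))
  expect_equal(pos, rbind(c(0, 1), c(1, 1)))    # tie broken by grid order

  # invariant to input permutation: equals brute-force sort-and-take
  set.seed(11)
  dens2 <- sample(0:20, 4, replace = TRUE)
  perm <- sample(4)
  a <- selectRois(tiles, topN = 3L, densities = dens2)
  b <- selectRois(tiles[perm], topN = 3L, densities = dens2[perm])
  expect_equal(lapply(a@rois, function(t) pixels(t@image)),
               lapply(b@rois, function(t) pixels(t@image)))
  expect_equal(sort(a@densities, decreasing = TRUE),
               sort(dens2, decreasing = TRUE)[1:3])

  # topN beyond the tile count returns everything
  expect_length(selectRois(tiles, topN = 99L, densities = dens)@rois, 4L)
  expect_error(selectRois(list(), topN = 2L), "empty")
})

test_that("nuclei density tracks ground-truth blob count on fixtures", {
  specs <- list(
    sparse = list(density = 8,  radius = 3.2, radiusSd = 0.4,
                  tint = c(225, 195, 220), noiseSd = 5),
    mid    = list(density = 25, radius = 3.0, radiusSd = 0.4,
                  tint = c(215, 180, 210), noiseSd = 6),
    dense  = list(density = 55, radius = 2.8, radiusSd = 0.4,
                  tint = c(200, 165, 200), noiseSd = 7))
  d <- generateTextureDataset(17, classes = specs, imageSize = 96, seed = 5)
  take <- seq_len(50)
  dens <- vapply(images(d)[take],
                 function(im) nucleiDensity(applyClahe(logNormalize(im))),
                 integer(1))
  rho <- cor(dens, d@meta$nucleiCount[take], method = "spearman")
  expect_gte(rho, 0.9)
})
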