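test_that("image read/write round-trips PNG and TIFF at declared depth", {
  z <- grayImage(matrix(0, 3, 3))
  p <- withr::local_tempfile(fileext = ".png")
  writeRaster(z, p)
  back <- readRaster(p)
  expect_equal(pixels(back), pixels(z))
  expect_identical(bitDepth(back), 8L)

  img <- rgbImage(randGray(5, 4, 1), randGray(5, 4, 2), randGray(5, 4, 3))
  p2 <- withr::local_tempfile(fileext = ".png")
  writeRaster(img, p2)
  expect_equal(pixels(readRaster(p2)), pixels(img))

  # 16-bit TIFF written by an independent writer, read back element-wise
  g16 <- matrix(c(0L, 65535L, 1234L, 40000L, 7L, 65535L), 2, 3)
  t16 <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(g16 / 65535, t16, bits.per.sample = 16L)
  r16 <- readRaster(t16)
  expect_identical(bitDepth(r16), 16L)
  expect_equal(as.vector(pixels(r16)), as.vector(g16))
  expect_equal(max(pixels(r16)), 65535)

  expect_error(readRaster(file.path(tempdir(), "absent.png")), "no such file")
})

test_that("synthetic dataset generation is deterministic and class-faithful", {
  a <- generateTextureDataset(3, imageSize = 48, seed = 7)
  b <- generateTextureDataset(3, imageSize = 48, seed = 7)
  expect_identical(lapply(images(a), pixels), lapply(images(b), pixels))
  expect_identical(a@meta$nucleiCount, b@meta$nucleiCount)
  expect_identical(imageLabels(a), imageLabels(b))

  # degenerate class: zero blob density leaves tint + noise only
  specs <- list(empty = list(density = 0, radius = 3, radiusSd = 0.3,
                             tint = c(200, 160, 200), noiseSd = 5))
  d <- generateTextureDataset(4, classes = specs, imageSize = 48, seed = 1)
  expect_true(all(d@meta$nucleiCount == 0))
  expect_true(all(abs(mean(pixels(images(d)[[1]])[, , 1]) - 200) < 3))

  expect_error(generateTextureDataset(2, imageSize = 16), "imageSize")
})

test_that("class tints separate the per-class red-channel means", {
  specs <- list(
    pink  = list(density = 10, radius = 3, radiusSd = 0.3,
                 tint = c(200, 160, 200), noiseSd = 5),
    green = list(density = 10, radius = 3, radiusSd = 0.3,
                 tint = c(160, 200, 160), noiseSd = 5))
  d <- generateTextureDataset(50, classes = specs, imageSize = 32, seed = 3)
  rmean <- vapply(images(d), function(im) mean(pixels(im)[, , 1]), numeric(1))
  byClass <- tapply(rmean, imageLabels(d), mean)
  expect_gt(byClass["pink"] - byClass["green"], 20)
})

test_that("right-angle rotations and flips are exact group operations", {
  img <- rgbImage(randGray(7, 5, 10), randGray(7, 5, 11), randGray(7, 5, 12))
  r <- img
  for (i in 1:4) r <- augmentImage(r, "rotate", k = 1)
  expect_equal(pixels(r), pixels(img))
  expect_equal(pixels(augmentImage(augmentImage(img, "flip", axis = "h"),
                                   "flip", axis = "h")), pixels(img))
  # histogram is preserved exactly by any rotation/flip
  r1 <- augmentImage(img, "rotate", k = 3)
  expect_equal(sort(as.vector(pixels(r1))), sort(as.vector(pixels(img))))
  f1 <- augmentImage(img, "flip", axis = "v")
  expect_equal(sort(as.vector(pixels(f1))), sort(as.vector(pixels(img))))
})

test_that("shift replicates edges; zoom keeps shape and range", {
  ramp <- grayImage(matrix(1:9, 3, 3, byrow = TRUE))
  sh <- augmentImage(ramp, "shift", dx = 1)
  # first column duplicated, rest shifted right
  expect_equal(pixels(sh),
               matrix(c(1, 1, 2, 4, 4, 5, 7, 7, 8), 3, 3, byrow = TRUE))
  expect_error(augmentImage(ramp, "shift", dx = 5), "magnitude")

  img <- grayImage(randGray(9, 9, 2))
  z <- augmentImage(img, "zoom", factor = 1.5)
  expect_identical(dim(pixels(z)), dim(pixels(img)))
  expect_true(all(pixels(z) >= 0 & pixels(z) <= 255))
  expect_error(augmentImage(img, "zoom", factor = 3), "factor")
  # zoom by 1 is the identity
  expect_equal(pixels(augmentImage(img, "zoom", factor = 1)), pixels(img))
})

test_that("feature tables round-trip CSV to at least 12 significant digits", {
  vals <- matrix(c(pi, exp(1), sqrt(2), 1 / 3, 1e-7, 123456.789), 2, 3,
                 dimnames = list(NULL, c("a.x", "a.y", "b.z")))
  tab <- FeatureTable(vals, labels = c("g1", "g2"),
                      parentId = c("p1", "p2"))
  f <- withr::local_tempfile(fileext = ".csv")
  writeFeatureTable(tab, f)
  back <- readFeatureTable(f)
  expect_equal(featureMatrix(back), featureMatrix(tab), tolerance = 1e-12)
  expect_identical(featureLabels(back), c("g1", "g2"))
  expect_identical(featureParents(back), c("p1", "p2"))

  # empty table round-trips as a header-only file
  e <- FeatureTable(matrix(numeric(), 0, 3,
                           dimnames = list(NULL, c("u", "v", "w"))))
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeFeatureTable(e, f2)
  expect_identical(length(readLines(f2)), 1L)
  expect_identical(colnames(featureMatrix(readFeatureTable(f2))),
                   c("u", "v", "w"))

  # ragged row is rejected with its row number
  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,b,c", "1,2,3", "4,5"), f3)
  expect_error(readFeatureTable(f3), "row 2")
})
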