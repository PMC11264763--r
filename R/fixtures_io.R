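#' Read a PNG or TIFF image into a RasterImage
#'
#' Supports 8- and 16-bit images with 1 or 3 channels.  Channel order of RGB
#' images is preserved as R,G,B.  The PNG bit depth is taken from the file
#' header; TIFF bit depth from the directory tags.
#'
#' @param path path to a .png, .tif or .tiff file
#' @return a \linkS4class{RasterImage}
#' @export
readRaster <- function(path) {
  if (!file.exists(path)) stop("cannot read image: no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    arr <- tryCatch(png::readPNG(path),
                    error = function(e) stop("unreadable PNG '", path, "': ",
                                             conditionMessage(e)))
    # IHDR bit depth is byte 25 of the file (8-byte signature + length+type)
    depth <- as.integer(readBin(path, "raw", n = 25L)[25L])
    if (!depth %in% c(8L, 16L)) stop("unsupported PNG bit depth: ", depth)
    mx <- 2^depth - 1
    px <- round(arr * mx)
  } else if (ext %in% c("tif", "tiff")) {
    px <- tryCatch(suppressWarnings(tiff::readTIFF(path, as.is = TRUE)),
                   error = function(e) stop("unreadable TIFF '", path, "': ",
                                            conditionMessage(e)))
    depth <- if (max(px) > 255 || isTRUE(attr(px, "bits.per.sample") == 16L))
      16L else 8L
    bps <- attr(tiff::readTIFF(path, info = TRUE), "bits.per.sample")
    if (!is.null(bps)) depth <- as.integer(bps)
  } else stop("unsupported image format: .", ext)
  d <- dim(px)
  if (length(d) == 3L) {
    if (d[3] == 1L) px <- px[, , 1L]
    else if (d[3] != 3L)
      stop("unsupported channel count (", d[3], ") in ", path)
  }
  RasterImage(as.array(px), bitDepth = depth)
}

#' Write a RasterImage to PNG (8-bit) or TIFF (8/16-bit)
#'
#' @param image a \linkS4class{RasterImage}
#' @param path destination; format chosen by extension
#' @return invisibly, \code{path}
#' @export
writeRaster <- function(image, path) {
  stopifnot(is(image, "RasterImage"))
  mx <- 2^image@bitDepth - 1
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    if (image@bitDepth != 8L) stop("PNG output is 8-bit; use TIFF for 16-bit")
    png::writePNG(image@pixels / mx, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(image@pixels / mx, path,
                    bits.per.sample = image@bitDepth)
  } else stop("unsupported image format: .", ext)
  invisible(path)
}

## Default synthetic class specifications.  Four classes emulating increasing
## glioma grade: nuclear density rises and mean nuclear radius falls with
## grade (cell proliferation), while the eosin-dominated background tint
## darkens/purples, so both second-order texture and color moments carry
## class signal.
defaultClassSpecs <- function() {
  list(
    oligodendroglioma = list(density = 12, radius = 3.6, radiusSd = 0.5,
                             tint = c(235, 205, 228), noiseSd = 5),
    astrocytoma       = list(density = 26, radius = 3.2, radiusSd = 0.5,
                             tint = c(222, 185, 216), noiseSd = 6),
    oligoastrocytoma  = list(density = 45, radius = 2.9, radiusSd = 0.4,
                             tint = c(206, 168, 204), noiseSd = 7),
    gbm               = list(density = 70, radius = 2.6, radiusSd = 0.4,
                             tint = c(188, 148, 192), noiseSd = 8)
  )
}

#' Generate a labeled synthetic texture dataset
#'
#' Procedural stand-in for H&E-stained histopathology tiles: each image is a
#' noisy background tint with dark, roughly circular "nuclei" blobs.  Class
#' specs control blob density (expected count per 128x128 area; per-image
#' counts are Poisson), blob radius
#' distribution, background tint and additive noise, so classes differ in
#' both second-order texture and color moments.  Deterministic given
#' \code{seed}; the true blob count per image is recorded in the set's
#' metadata.
#'
#' @param nPerClass images per class (>= 1)
#' @param classes named list of class specs (fields \code{density},
#'   \code{radius}, \code{radiusSd}, \code{tint}, \code{noiseSd});
#'   defaults emulate four histologic types of increasing grade
#' @param imageSize side length in pixels (>= 32)
#' @param seed integer RNG seed
#' @return a \linkS4class{LabeledImageSet} with \code{meta$nucleiCount}
#' @examples
#' set <- generateTextureDataset(2, imageSize = 64, seed = 1)
#' set
#' @export
generateTextureDataset <- function(nPerClass, classes = defaultClassSpecs(),
                                   imageSize = 128, seed = 0) {
  if (nPerClass < 1) stop("nPerClass must be >= 1")
  if (imageSize < 32) stop("imageSize must be >= 32")
  codebook <- names(classes)
  if (is.null(codebook)) stop("classes must be a named list")
  withSeed(seed, {
    imgs <- list(); labs <- character(); counts <- integer()
    nucleusColor <- c(92, 58, 124)   # hematoxylin-like dark purple
    for (cls in codebook) {
      sp <- classes[[cls]]
      for (i in seq_len(nPerClass)) {
        n <- stats::rpois(1L, sp$density * (imageSize / 128)^2)
        px <- array(0, c(imageSize, imageSize, 3))
        for (ch in 1:3)
          px[, , ch] <- sp$tint[ch] +
            matrix(rnorm(imageSize^2, 0, sp$noiseSd), imageSize)
        if (n > 0) {
          cr <- runif(n, 1, imageSize); cc <- runif(n, 1, imageSize)
          rad <- pmax(1.2, rnorm(n, sp$radius, sp$radiusSd))
          shade <- runif(n, 0.85, 1.15)
          rows <- matrix(seq_len(imageSize), imageSize, imageSize)
          cols <- t(rows)
          for (b in seq_len(n)) {
            d2 <- (rows - cr[b])^2 + (cols - cc[b])^2
            inside <- d2 <= rad[b]^2
            if (any(inside)) {
              for (ch in 1:3) {
                plane <- px[, , ch]
                plane[inside] <- nucleusColor[ch] * shade[b] +
                  rnorm(sum(inside), 0, 2)
                px[, , ch] <- plane
              }
            }
          }
        }
        px <- pmin(pmax(round(px), 0), 255)
        imgs[[length(imgs) + 1L]] <- RasterImage(px, 8L)
        labs <- c(labs, cls)
        counts <- c(counts, if (is.null(n)) 0L else n)
      }
    }
    new("LabeledImageSet", images = imgs, labels = labs, codebook = codebook,
        seed = as.integer(seed),
        meta = data.frame(nucleiCount = counts,
                          id = sprintf("%s_%02d", labs,
                                       stats::ave(seq_along(labs), labs,
                                                  FUN = seq_along))))
  })
}

# bilinear sample of a single channel at fractional (row, col) positions,
# with edge replication outside the support
bilinearSample <- function(m, r, c) {
  H <- nrow(m); W <- ncol(m)
  r <- pmin(pmax(r, 1), H); c <- pmin(pmax(c, 1), W)
  r0 <- floor(r); c0 <- floor(c)
  r1 <- pmin(r0 + 1, H); c1 <- pmin(c0 + 1, W)
  fr <- r - r0; fc <- c - c0
  m[cbind(r0, c0)] * (1 - fr) * (1 - fc) + m[cbind(r1, c0)] * fr * (1 - fc) +
    m[cbind(r0, c1)] * (1 - fr) * fc + m[cbind(r1, c1)] * fr * fc
}

#' Augment an image by rotation, flip, shift or zoom
#'
#' Right-angle rotations and axis flips are exact (lossless index
#' permutations).  Shifts replicate edge pixels into the vacated band; zoom
#' resamples about the image center with bilinear interpolation and edge
#' replication, so the output always has the input's shape.
#'
#' @param image a \linkS4class{RasterImage}
#' @param op one of \code{"rotate"}, \code{"flip"}, \code{"shift"},
#'   \code{"zoom"}
#' @param k rotation quarter-turns (rotate; counter-clockwise)
#' @param axis \code{"h"} or \code{"v"} (flip)
#' @param dx,dy column/row shift in pixels (shift)
#' @param factor zoom factor in [0.5, 2] (zoom; > 1 magnifies)
#' @return a \linkS4class{RasterImage} of identical shape
#' @export
augmentImage <- function(image, op = c("rotate", "flip", "shift", "zoom"),
                         k = 1L, axis = c("h", "v"), dx = 0L, dy = 0L,
                         factor = 1) {
  stopifnot(is(image, "RasterImage"))
  op <- match.arg(op)
  px <- image@pixels
  nc <- nChannels(image)
  ch <- function(i) if (nc == 1L) px else px[, , i]
  planes <- lapply(seq_len(nc), ch)
  H <- nrow(planes[[1]]); W <- ncol(planes[[1]])
  out <- switch(op,
    rotate = {
      k <- as.integer(k) %% 4L
      lapply(planes, function(m) {
        for (i in seq_len(k)) m <- t(m)[rev(seq_len(ncol(m))), , drop = FALSE]
        m
      })
    },
    flip = {
      axis <- match.arg(axis)
      lapply(planes, function(m)
        if (axis == "h") m[, rev(seq_len(W)), drop = FALSE]
        else m[rev(seq_len(H)), , drop = FALSE])
    },
    shift = {
      if (abs(dx) >= W || abs(dy) >= H) stop("shift magnitude exceeds image size")
      src_r <- pmin(pmax(seq_len(H) - as.integer(dy), 1L), H)
      src_c <- pmin(pmax(seq_len(W) - as.integer(dx), 1L), W)
      lapply(planes, function(m) m[src_r, src_c, drop = FALSE])
    },
    zoom = {
      if (factor < 0.5 || factor > 2) stop("zoom factor must be in [0.5, 2]")
      cr <- (H + 1) / 2; cc <- (W + 1) / 2
      g <- expand.grid(r = seq_len(H), c = seq_len(W))
      sr <- cr + (g$r - cr) / factor
      sc <- cc + (g$c - cc) / factor
      lapply(planes, function(m) matrix(bilinearSample(m, sr, sc), H, W))
    })
  res <- if (nc == 1L) out[[1]] else {
    a <- array(0, c(nrow(out[[1]]), ncol(out[[1]]), 3L))
    for (i in 1:3) a[, , i] <- out[[i]]
    a
  }
  RasterImage(res, image@bitDepth)
}

#' Write / read a feature table as CSV
#'
#' CSV with a header row; values serialized with 15 significant digits so a
#' round trip reproduces them to at least 12 significant digits.  Optional
#' \code{label} and \code{parent_id} columns carry row annotation.
#'
#' @param table a \linkS4class{FeatureTable}
#' @param path CSV destination / source
#' @return \code{writeFeatureTable}: invisibly \code{path};
#'   \code{readFeatureTable}: a \linkS4class{FeatureTable}
#' @export
writeFeatureTable <- function(table, path) {
  stopifnot(is(table, "FeatureTable"))
  df <- as.data.frame(table@values, check.names = FALSE)
  if (length(table@labels)) df <- cbind(label = table@labels, df)
  if (length(table@parentId)) df <- cbind(parent_id = table@parentId, df)
  fmt <- df
  num <- vapply(fmt, is.numeric, logical(1))
  fmt[num] <- lapply(fmt[num], function(v) formatC(v, digits = 15,
                                                   format = "g"))
  utils::write.csv(fmt, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  if (!length(lines)) stop("empty feature table file: ", path)
  ncols <- length(strsplit(lines[1], ",", fixed = TRUE)[[1]])
  bad <- which(vapply(strsplit(lines, ",", fixed = TRUE), length,
                      integer(1)) != ncols)
  if (length(bad))
    stop("ragged feature table: row ", bad[1] - 1L, " of ", path,
         " has the wrong column count")
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = NA, stringsAsFactors = FALSE)
  labels <- character(); parents <- character()
  if ("parent_id" %in% names(df)) {
    parents <- as.character(df$parent_id); df$parent_id <- NULL
  }
  if ("label" %in% names(df)) {
    labels <- as.character(df$label); df$label <- NULL
  }
  vals <- as.matrix(df)
  if (nrow(vals) == 0) vals <- matrix(numeric(), 0, ncol(df),
                                      dimnames = list(NULL, names(df)))
  storage.mode(vals) <- "double"
  FeatureTable(vals, labels = labels, parentId = parents)
}
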