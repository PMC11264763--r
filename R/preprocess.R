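#' Global log-normalization of image contrast
#'
#' Per channel, maps intensity I to
#' \code{round((2^b - 1) * log(1 + I) / log(1 + Imax))} where \code{Imax} is
#' that channel's maximum and \code{b} the bit depth.  A constant
#' all-zero channel stays zero; otherwise endpoints 0 and \code{Imax} are
#' fixed and the map is monotone non-decreasing, boosting dark-range
#' contrast before local equalization.
#'
#' @param image a \linkS4class{RasterImage}
#' @return a \linkS4class{RasterImage} of the same shape and depth
#' @export
logNormalize <- function(image) {
  stopifnot(is(image, "RasterImage"))
  mx <- 2^image@bitDepth - 1
  f <- function(m) {
    iMax <- max(m)
    if (iMax == 0) return(m)
    round(mx * log1p(m) / log1p(iMax))
  }
  px <- image@pixels
  if (nChannels(image) == 1L) px <- f(px)
  else for (i in 1:3) px[, , i] <- f(px[, , i])
  RasterImage(px, image@bitDepth)
}

#' Contrast-limited adaptive histogram equalization
#'
#' Divides the image into a grid of contextual regions, equalizes each
#' region's histogram with clipping and redistribution, and blends adjacent
#' region mappings bilinearly.  Color images are equalized on the HSV value
#' channel and recombined, preserving hue.
#'
#' @param image a \linkS4class{RasterImage}
#' @param grid integer length-2, contextual regions per axis (default 8x8;
#'   minimum 2 per axis)
#' @param clipLimit clip limit as a multiple of the uniform histogram level
#' @return a \linkS4class{RasterImage}
#' @export
applyClahe <- function(image, grid = c(8L, 8L), clipLimit = 4) {
  stopifnot(is(image, "RasterImage"))
  if (image@bitDepth != 8L) stop("CLAHE is applied to 8-bit images")
  grid <- as.integer(rep(grid, length.out = 2L))
  if (any(grid < 2L)) stop("grid must be at least 2 regions per axis")
  d <- dim(image@pixels)
  if (d[1] < grid[1] * 2 || d[2] < grid[2] * 2)
    stop("image smaller than the CLAHE grid")
  eq <- function(m) {
    if (max(m) == min(m)) return(m)   # no contrast to equalize
    # EBImage works on x-y (col-major transposed) images in [0,1]
    y <- EBImage::clahe(t(m) / 255, nx = grid[2], ny = grid[1],
                        bins = 256L, limit = clipLimit, keep.range = TRUE)
    pmin(pmax(round(t(y) * 255), 0), 255)
  }
  if (nChannels(image) == 1L)
    return(RasterImage(eq(image@pixels), 8L))
  px <- image@pixels
  r <- px[, , 1]; g <- px[, , 2]; b <- px[, , 3]
  v <- pmax(r, pmax(g, b))                   # HSV value channel
  v2 <- eq(v)
  scale <- ifelse(v > 0, v2 / v, 0)
  out <- array(0, dim(px))
  out[, , 1] <- pmin(pmax(round(r * scale), 0), 255)
  out[, , 2] <- pmin(pmax(round(g * scale), 0), 255)
  out[, , 3] <- pmin(pmax(round(b * scale), 0), 255)
  RasterImage(out, 8L)
}

#' Cut an image into non-overlapping square tiles
#'
#' Tiles are emitted in row-major order with 0-based grid positions; the
#' right/bottom remainder that does not fill a whole tile is discarded.  An
#' image smaller than one tile is returned as a single edge-padded tile only
#' when \code{pad = TRUE}.
#'
#' @param image a \linkS4class{RasterImage}
#' @param tileSize tile side in pixels (default 512)
#' @param parentId identifier recorded on each tile
#' @param pad pad an undersized image to one full tile instead of erroring
#' @return list of \linkS4class{Tile}
#' @export
tileImage <- function(image, tileSize = 512L, parentId = "image", pad = FALSE) {
  stopifnot(is(image, "RasterImage"))
  d <- dim(image@pixels); H <- d[1]; W <- d[2]
  tileSize <- as.integer(tileSize)
  if (H < tileSize || W < tileSize) {
    if (!pad) stop("image (", H, "x", W, ") smaller than one ", tileSize,
                   "-pixel tile; set pad=TRUE to pad")
    ri <- pmin(seq_len(tileSize), H); ci <- pmin(seq_len(tileSize), W)
    px <- if (nChannels(image) == 1L) image@pixels[ri, ci, drop = FALSE]
          else image@pixels[ri, ci, , drop = FALSE]
    return(list(new("Tile", image = RasterImage(px, image@bitDepth),
                    parentId = parentId, gridRow = 0L, gridCol = 0L)))
  }
  nr <- H %/% tileSize; nc <- W %/% tileSize
  tiles <- vector("list", nr * nc)
  idx <- 1L
  for (i in seq_len(nr) - 1L) for (j in seq_len(nc) - 1L) {
    ri <- (i * tileSize + 1L):((i + 1L) * tileSize)
    ci <- (j * tileSize + 1L):((j + 1L) * tileSize)
    px <- if (nChannels(image) == 1L) image@pixels[ri, ci, drop = FALSE]
          else image@pixels[ri, ci, , drop = FALSE]
    tiles[[idx]] <- new("Tile", image = RasterImage(px, image@bitDepth),
                        parentId = parentId, gridRow = i, gridCol = j)
    idx <- idx + 1L
  }
  tiles
}

# Rec.601 luminance of a RasterImage, on the raw intensity scale
luminance <- function(image) {
  if (nChannels(image) == 1L) return(image@pixels)
  px <- image@pixels
  0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
}

#' Count nuclei in a tile by watershed segmentation
#'
#' Fixed pipeline: luminance, Otsu threshold for dark objects, Euclidean
#' distance transform, watershed with peak-merging tolerance, then count of
#' segments whose area lies within \code{areaRange}.  Deterministic for
#' fixed parameters; a blank (constant) tile yields 0.
#'
#' @param tile a \linkS4class{Tile} or \linkS4class{RasterImage} (8-bit)
#' @param areaRange admissible segment area in pixels
#' @param tolerance watershed peak-merging tolerance (intensity units of the
#'   distance map)
#' @param ext peak neighborhood radius in pixels (about one expected
#'   nucleus radius)
#' @return integer nuclei count
#' @export
nucleiDensity <- function(tile, areaRange = c(8, 2000), tolerance = 0.5,
                          ext = 2) {
  img <- if (is(tile, "Tile")) tile@image else tile
  stopifnot(is(img, "RasterImage"))
  lum <- luminance(img) / (2^img@bitDepth - 1)
  if (max(lum) - min(lum) < 1e-9) return(0L)
  thr <- EBImage::otsu(EBImage::Image(t(lum)), range = c(0, 1))
  mask <- lum < thr                           # nuclei are dark on light
  if (!any(mask)) return(0L)
  dm <- EBImage::distmap(EBImage::Image(t(mask)))
  ws <- EBImage::watershed(dm, tolerance = tolerance, ext = ext)
  areas <- tabulate(as.integer(ws))
  sum(areas >= areaRange[1] & areas <= areaRange[2])
}

#' Select the highest nuclear-density tiles as regions of interest
#'
#' Returns the \code{topN} tiles ranked by density; ties are broken by
#' (gridRow, gridCol) order, so the result is invariant to the input
#' ordering of \code{tiles}.
#'
#' @param tiles list of \linkS4class{Tile}
#' @param topN number of ROIs to keep (default 5)
#' @param densities optional pre-computed densities (same order as tiles);
#'   computed with \code{\link{nucleiDensity}} when missing
#' @param ... passed to \code{\link{nucleiDensity}}
#' @return a \linkS4class{ROISet}
#' @export
selectRois <- function(tiles, topN = 5L, densities = NULL, ...) {
  if (!length(tiles)) stop("empty tile list")
  if (is.null(densities))
    densities <- vapply(tiles, nucleiDensity, numeric(1), ...)
  if (length(densities) != length(tiles))
    stop("densities must match tiles")
  gr <- vapply(tiles, function(t) t@gridRow, integer(1))
  gc <- vapply(tiles, function(t) t@gridCol, integer(1))
  ord <- order(-densities, gr, gc)
  keep <- ord[seq_len(min(topN, length(tiles)))]
  new("ROISet", rois = tiles[keep], densities = as.numeric(densities[keep]),
      topN = as.integer(topN))
}
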