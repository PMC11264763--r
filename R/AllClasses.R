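#' @import methods
NULL

#' RasterImage: an integer-valued intensity grid
#'
#' Container for a grayscale (height x width) or RGB (height x width x 3)
#' image with an explicit bit depth.  Pixels are stored as numeric values on
#' the integer scale \code{[0, 2^bitDepth - 1]}; the coordinate convention
#' throughout the package is top-left origin, row-major, 0-based when grid
#' positions are reported.
#'
#' @slot pixels numeric matrix (gray) or 3-d array (RGB, channel order R,G,B)
#' @slot bitDepth integer, bits per channel (8 or 16)
#'
#' @examples
#' img <- RasterImage(matrix(0:24, 5, 5), bitDepth = 8L)
#' dim(pixels(img))
#' @export
setClass("RasterImage",
  representation(pixels = "array", bitDepth = "integer"),
  validity = function(object) {
    d <- dim(object@pixels)
    if (!(length(d) == 2L || (length(d) == 3L && d[3] %in% c(1L, 3L))))
      return("pixels must be height x width or height x width x {1,3}")
    if (!(object@bitDepth %in% c(8L, 16L)))
      return("bitDepth must be 8 or 16")
    mx <- 2^object@bitDepth - 1
    v <- object@pixels
    if (anyNA(v) || any(v < 0) || any(v > mx))
      return(sprintf("intensities must lie in [0, %d]", mx))
    TRUE
  })

#' @rdname RasterImage-class
#' @param pixels numeric matrix or array of intensities
#' @param bitDepth bits per channel
#' @export
RasterImage <- function(pixels, bitDepth = 8L) {
  if (is.vector(pixels)) stop("pixels must be a matrix or 3-d array")
  new("RasterImage", pixels = as.array(pixels), bitDepth = as.integer(bitDepth))
}

#' @describeIn RasterImage-class intensity array accessor
#' @param x a RasterImage
#' @export
pixels <- function(x) x@pixels

#' @describeIn RasterImage-class bits per channel
#' @export
bitDepth <- function(x) x@bitDepth

#' @describeIn RasterImage-class number of channels (1 or 3)
#' @export
nChannels <- function(x) if (length(dim(x@pixels)) == 3L) dim(x@pixels)[3] else 1L

setMethod("show", "RasterImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("RasterImage %d x %d, %d channel(s), %d-bit\n",
              d[1], d[2], nChannels(object), object@bitDepth))
})

#' LabeledImageSet: images with grade labels
#'
#' A list of \linkS4class{RasterImage} objects with one class label per
#' image, the ordered label codebook, the seed the set was generated from
#' and per-image metadata (for synthetic sets, the ground-truth nuclei
#' count).
#'
#' @slot images list of RasterImage
#' @slot labels character, one label per image
#' @slot codebook ordered class names
#' @slot seed integer seed used for generation (NA for read-in sets)
#' @slot meta data.frame of per-image metadata (may have 0 columns)
#' @export
setClass("LabeledImageSet",
  representation(images = "list", labels = "character",
                 codebook = "character", seed = "integer", meta = "data.frame"),
  validity = function(object) {
    if (length(object@images) != length(object@labels))
      return("|images| must equal |labels|")
    if (!all(object@labels %in% object@codebook))
      return("every label must be in the codebook")
    if (nrow(object@meta) > 0 && nrow(object@meta) != length(object@images))
      return("meta rows must match images")
    TRUE
  })

setMethod("show", "LabeledImageSet", function(object) {
  cat(sprintf("LabeledImageSet: %d images, %d classes (%s)\n",
              length(object@images), length(object@codebook),
              paste(object@codebook, collapse = ", ")))
})

#' @describeIn LabeledImageSet-class image list accessor
#' @param x a LabeledImageSet
#' @export
images <- function(x) x@images

#' @describeIn LabeledImageSet-class label accessor
#' @export
imageLabels <- function(x) x@labels

#' Tile: one sub-image cut from a parent image
#'
#' @slot image RasterImage of the tile
#' @slot parentId identifier of the source image
#' @slot gridRow,gridCol 0-based grid position within the parent
#' @export
setClass("Tile",
  representation(image = "RasterImage", parentId = "character",
                 gridRow = "integer", gridCol = "integer"))

setMethod("show", "Tile", function(object) {
  cat(sprintf("Tile (%d,%d) of '%s': ", object@gridRow, object@gridCol,
              object@parentId))
  show(object@image)
})

#' ROISet: the highest nuclear-density tiles of one parent image
#'
#' @slot rois list of Tile, ordered by decreasing density (ties in grid order)
#' @slot densities nuclei count for each retained tile
#' @slot topN number of tiles requested
#' @export
setClass("ROISet",
  representation(rois = "list", densities = "numeric", topN = "integer"),
  validity = function(object) {
    if (length(object@rois) != length(object@densities))
      return("densities must match rois")
    TRUE
  })

setMethod("show", "ROISet", function(object) {
  cat(sprintf("ROISet: %d ROI(s) of %d requested; densities: %s\n",
              length(object@rois), object@topN,
              paste(object@densities, collapse = ", ")))
})

#' CooccurrenceMatrix: normalized gray-level co-occurrence counts
#'
#' @slot p levels x levels probability matrix (sums to 1)
#' @slot levels number of quantized gray levels
#' @slot angle offset direction in degrees (0, 45, 90 or 135; distance 1)
#' @slot symmetric whether the transpose was added before normalization
#' @export
setClass("CooccurrenceMatrix",
  representation(p = "matrix", levels = "integer", angle = "numeric",
                 symmetric = "logical"),
  validity = function(object) {
    if (any(object@p < 0)) return("entries must be non-negative")
    if (abs(sum(object@p) - 1) > 1e-9) return("entries must sum to 1")
    if (object@symmetric && max(abs(object@p - t(object@p))) > 0)
      return("symmetric mode requires p == t(p)")
    TRUE
  })

setMethod("show", "CooccurrenceMatrix", function(object) {
  cat(sprintf("CooccurrenceMatrix: %d levels, %g deg, symmetric=%s\n",
              object@levels, object@angle, object@symmetric))
})

#' RunLengthMatrix: gray-level run-length counts for one scan direction
#'
#' @slot counts nGray x maxRunLength matrix of run counts
#' @slot p normalized counts (sum to 1 over all cells)
#' @slot nGray number of gray levels
#' @slot angle scan direction in degrees
#' @slot muG mean gray level of the scanned pixels (1-based level units)
#' @slot muR mean run length of this direction's runs
#' @slot nPixels number of pixels scanned
#' @export
setClass("RunLengthMatrix",
  representation(counts = "matrix", p = "matrix", nGray = "integer",
                 angle = "numeric", muG = "numeric", muR = "numeric",
                 nPixels = "integer"),
  validity = function(object) {
    if (any(object@counts < 0)) return("counts must be non-negative")
    if (abs(sum(object@p) - 1) > 1e-9) return("p must sum to 1")
    TRUE
  })

setMethod("show", "RunLengthMatrix", function(object) {
  cat(sprintf("RunLengthMatrix: %d gray levels, runs up to %d, %g deg\n",
              object@nGray, ncol(object@counts), object@angle))
})

#' LBPMap: per-pixel local binary pattern codes
#'
#' @slot codes integer matrix of LBP codes (borders excluded)
#' @slot P number of circular neighbors
#' @slot R neighborhood radius in pixels
#' @slot variant "basic" (codes 0..2^P-1) or "riu2" (codes 0..P+1)
#' @export
setClass("LBPMap",
  representation(codes = "matrix", P = "integer", R = "numeric",
                 variant = "character"),
  validity = function(object) {
    top <- if (object@variant == "riu2") object@P + 1 else 2^object@P - 1
    if (any(object@codes < 0) || any(object@codes > top))
      return("codes out of range for variant")
    TRUE
  })

setMethod("show", "LBPMap", function(object) {
  cat(sprintf("LBPMap: P=%d R=%g variant=%s, %d x %d\n", object@P, object@R,
              object@variant, nrow(object@codes), ncol(object@codes)))
})

#' HeterogeneityMaps: per-pixel variance and homogeneity
#'
#' @slot varianceMap per-pixel second moment of the circular neighborhood
#' @slot homogeneityMap per-pixel local homogeneity (<= 1; 1 when constant)
#' @slot P,R neighborhood geometry (as the matching LBPMap)
#' @export
setClass("HeterogeneityMaps",
  representation(varianceMap = "matrix", homogeneityMap = "matrix",
                 P = "integer", R = "numeric"),
  validity = function(object) {
    if (any(object@varianceMap < -1e-9)) return("variance must be >= 0")
    if (any(object@homogeneityMap > 1 + 1e-9)) return("homogeneity must be <= 1")
    TRUE
  })

#' FeatureTable: one feature vector per ROI
#'
#' Rows are ROIs, columns are block-prefixed feature names (e.g.
#' \code{glcm.contrast}).  Labels and the parent-image identifier travel with
#' the rows so grouped resampling can keep all ROIs of one parent on one
#' side of a split.
#'
#' @slot values numeric matrix, rownames free, colnames globally unique
#' @slot labels character labels per row (length 0 when unlabeled)
#' @slot parentId parent-image id per row (length 0 when unknown)
#' @export
setClass("FeatureTable",
  representation(values = "matrix", labels = "character", parentId = "character"),
  validity = function(object) {
    if (length(object@labels) && length(object@labels) != nrow(object@values))
      return("labels must match rows")
    if (length(object@parentId) && length(object@parentId) != nrow(object@values))
      return("parentId must match rows")
    if (anyDuplicated(colnames(object@values)))
      return("column names must be unique")
    if (any(!is.finite(object@values)))
      return("feature values must be finite")
    TRUE
  })

#' @rdname FeatureTable-class
#' @param values numeric matrix with unique column names
#' @param labels optional character labels per row
#' @param parentId optional parent-image id per row
#' @export
FeatureTable <- function(values, labels = character(), parentId = character()) {
  new("FeatureTable", values = values, labels = as.character(labels),
      parentId = as.character(parentId))
}

#' @describeIn FeatureTable-class numeric matrix accessor
#' @param x a FeatureTable
#' @export
featureMatrix <- function(x) x@values

#' @describeIn FeatureTable-class row label accessor
#' @export
featureLabels <- function(x) x@labels

#' @describeIn FeatureTable-class parent-image id accessor
#' @export
featureParents <- function(x) x@parentId

setMethod("show", "FeatureTable", function(object) {
  cat(sprintf("FeatureTable: %d ROIs x %d features%s\n",
              nrow(object@values), ncol(object@values),
              if (length(object@labels)) sprintf(", %d classes",
                  length(unique(object@labels))) else ""))
})

#' ReducedBasis: a fitted non-negative matrix factorization
#'
#' Factor pair of X ~ W H with W (samples x k) the reduced representation
#' and H (k x features) the basis loadings.
#'
#' @slot W samples x k non-negative matrix
#' @slot H k x features non-negative matrix
#' @slot k factorization rank
#' @slot fitError final Frobenius norm of X - W H
#' @slot errorTrace per-iteration Frobenius error (non-increasing)
#' @slot featureNames column names of the fitted table
#' @export
setClass("ReducedBasis",
  representation(W = "matrix", H = "matrix", k = "integer",
                 fitError = "numeric", errorTrace = "numeric",
                 featureNames = "character"),
  validity = function(object) {
    if (any(object@W < 0) || any(object@H < 0))
      return("W and H must be non-negative")
    if (ncol(object@W) != object@k || nrow(object@H) != object@k)
      return("inner dimension must equal k")
    TRUE
  })

setMethod("show", "ReducedBasis", function(object) {
  cat(sprintf("ReducedBasis: k=%d, %d samples x %d features, fit error %.4g\n",
              object@k, nrow(object@W), ncol(object@H), object@fitError))
})

#' TrainedEnsemble: the three base classifiers plus the voting rule
#'
#' Base models are kept in the fixed order (RBF-SVM, fast large margin,
#' random tree); the majority vote breaks three-way ties in favour of the
#' first model in that order.
#'
#' @slot models list of the three fitted base models
#' @slot codebook ordered class labels
#' @slot hyper list of chosen hyper-parameters per model
#' @export
setClass("TrainedEnsemble",
  representation(models = "list", codebook = "character", hyper = "list"),
  validity = function(object) {
    if (length(object@models) != 3L) return("exactly 3 base models required")
    TRUE
  })

setMethod("show", "TrainedEnsemble", function(object) {
  cat(sprintf("TrainedEnsemble: %s | classes: %s\n",
              paste(names(object@models), collapse = " + "),
              paste(object@codebook, collapse = ", ")))
})

# run an expression under a fixed seed without disturbing the caller's RNG
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
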