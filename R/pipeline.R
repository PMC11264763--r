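#' Default pipeline configuration
#'
#' All tunable parameters of the grading pipeline with their defaults:
#' contrast enhancement, tiling/ROI selection, per-family feature
#' parameters and the reduction rank.  Any entry can be overridden through
#' the \code{...} of \code{\link{pipelineConfig}}.
#'
#' @param ... named overrides of the defaults
#' @return named list of parameters
#' @export
pipelineConfig <- function(...) {
  cfg <- list(
    claheGrid = c(8L, 8L), claheClip = 4,
    tileSize = 512L, topRois = 5L,
    nucleiArea = c(8, 2000), watershedTolerance = 0.5, watershedExt = 2,
    glcmLevels = 64L, glrlmLevels = 16L,
    lbpConfigs = list(c(8, 1), c(16, 2), c(24, 3)),
    hetP = 8L, hetR = 1,
    pyramidLevels = 3L, lbglcmLevels = c(128L, 64L, 64L),
    histBins = 8L, rshdShades = 64L,
    homogeneityForm = "printed", glrlmFormulas = "printed", moments = "root",
    nmfK = 32L, nmfIter = 300L
  )
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Enhance an image and select its regions of interest
#'
#' The two-step contrast enhancement (global log-normalization then CLAHE)
#' followed by tiling and nuclear-density ROI selection.  Images no larger
#' than one tile are processed as a single ROI.
#'
#' @param image an RGB 8-bit \linkS4class{RasterImage}
#' @param config a \code{\link{pipelineConfig}} list
#' @param parentId identifier recorded on the tiles
#' @return a \linkS4class{ROISet} of enhanced tiles
#' @export
preprocessImage <- function(image, config = pipelineConfig(),
                            parentId = "image") {
  enhanced <- applyClahe(logNormalize(image), grid = config$claheGrid,
                         clipLimit = config$claheClip)
  tiles <- tileImage(enhanced, tileSize = config$tileSize,
                     parentId = parentId, pad = TRUE)
  selectRois(tiles, topN = config$topRois,
             areaRange = config$nucleiArea,
             tolerance = config$watershedTolerance, ext = config$watershedExt)
}

#' Extract all six feature families from one ROI
#'
#' Families, in fixed order: GLCM statistics (four-direction average),
#' GLRLM statistics, multi-resolution riu2 LBP histograms plus the
#' heterogeneity-weighted variants, the multi-scale pyramid LBGLCM block,
#' color features (RGB/HSV moments and channel histograms) and the RSHD
#' descriptor.  Returns raw (unscaled) features; scaling happens at fusion
#' time with training-fold statistics.
#'
#' @param image an RGB 8-bit \linkS4class{RasterImage} (an ROI tile)
#' @param config a \code{\link{pipelineConfig}} list
#' @return named numeric vector with block-prefixed names
#' @export
extractFeatures <- function(image, config = pipelineConfig()) {
  stopifnot(is(image, "RasterImage"))
  gray <- luminance(image)
  qGlcm <- quantizeGray(gray, config$glcmLevels, image@bitDepth)
  glcm <- glcmFeatures(computeGlcm(qGlcm, config$glcmLevels),
                       homogeneityForm = config$homogeneityForm)
  names(glcm) <- paste0("glcm.", names(glcm))
  qRl <- quantizeGray(gray, config$glrlmLevels, image@bitDepth)
  glrlm <- glrlmFeatures(computeGlrlm(qRl, config$glrlmLevels),
                         formulas = config$glrlmFormulas)
  names(glrlm) <- paste0("glrlm.", names(glrlm))
  lbp <- lbpHistogramFeatures(gray, config$lbpConfigs)
  names(lbp) <- paste0("lbp.", names(lbp))
  map <- lbpMap(gray, config$hetP, config$hetR, variant = "riu2")
  het <- heterogeneityMaps(gray, config$hetP, config$hetR)
  wv <- heterogeneityWeightedLbp(map, het, mode = "variance")
  names(wv) <- sprintf("lbpw.var.%s", names(wv))
  wd <- heterogeneityWeightedLbp(map, het, mode = "dissimilarity")
  names(wd) <- sprintf("lbpw.dis.%s", names(wd))
  ms <- multiscaleLbglcm(gray, nLevels = config$pyramidLevels,
                         levels = config$lbglcmLevels)
  names(ms) <- paste0("lbglcm_ms.", names(ms))
  cm <- c(colorMoments(image, moments = config$moments),
          hsvMoments(image, moments = config$moments))
  hist <- colorHistogram(image, bins = config$histBins)
  hv <- unlist(lapply(names(hist), function(ch)
    stats::setNames(hist[[ch]] / sum(hist[[ch]]),
                    sprintf("hist.%s.bin%d", ch,
                            seq_along(hist[[ch]]) - 1L))))
  rs <- rshd(image, shades = config$rshdShades)
  names(rs) <- paste0("rshd.", names(rs))
  c(glcm, glrlm, lbp, wv, wd, ms, cm, hv, rs)
}

#' Extract the full feature table of a labeled image set
#'
#' Runs preprocessing and ROI selection on every image and extracts the
#' six feature families from each ROI.  One row per ROI; labels and the
#' parent-image id travel with the rows for grouped resampling.
#'
#' @param set a \linkS4class{LabeledImageSet}
#' @param config a \code{\link{pipelineConfig}} list
#' @param preprocess run enhancement + ROI selection first (set FALSE to
#'   extract from whole images as-is)
#' @return a labeled \linkS4class{FeatureTable}
#' @export
extractFeatureTable <- function(set, config = pipelineConfig(),
                                preprocess = TRUE) {
  stopifnot(is(set, "LabeledImageSet"))
  ids <- if ("id" %in% names(set@meta)) set@meta$id
         else sprintf("img%03d", seq_along(set@images))
  rows <- list(); labs <- character(); parents <- character()
  for (i in seq_along(set@images)) {
    rois <- if (preprocess)
      preprocessImage(set@images[[i]], config, parentId = ids[i])@rois
    else list(new("Tile", image = set@images[[i]], parentId = ids[i],
                  gridRow = 0L, gridCol = 0L))
    for (tile in rois) {
      rows[[length(rows) + 1L]] <- extractFeatures(tile@image, config)
      labs <- c(labs, set@labels[i])
      parents <- c(parents, ids[i])
    }
  }
  FeatureTable(do.call(rbind, rows), labels = labs, parentId = parents)
}
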