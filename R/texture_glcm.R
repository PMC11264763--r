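## Offsets (row, col) for the four standard co-occurrence directions at
## distance 1, in image coordinates (row increases downward):
## 0 deg -> (0,1); 45 deg -> (-1,1); 90 deg -> (-1,0); 135 deg -> (-1,-1).
glcmOffsets <- function() {
  list(`0` = c(0L, 1L), `45` = c(-1L, 1L), `90` = c(-1L, 0L),
       `135` = c(-1L, -1L))
}

#' Uniform gray-level quantization
#'
#' Bins the full intensity range of the declared bit depth into
#' \code{levels} uniform bins: value v maps to
#' \code{floor(v * levels / 2^bitDepth)}, clipped to \code{levels - 1}.
#'
#' @param gray numeric matrix of intensities, or a gray
#'   \linkS4class{RasterImage}
#' @param levels number of quantization levels (2..256)
#' @param bitDepth bit depth of the input scale (taken from the image when
#'   a RasterImage is given)
#' @return integer matrix of levels in \code{0..levels-1}
#' @export
quantizeGray <- function(gray, levels = 64L, bitDepth = 8L) {
  if (is(gray, "RasterImage")) {
    bitDepth <- gray@bitDepth
    gray <- luminance(gray)
  }
  levels <- as.integer(levels)
  if (levels < 2L || levels > 256L) stop("levels must be in 2..256")
  q <- floor(gray * levels / 2^bitDepth)
  matrix(as.integer(pmin(q, levels - 1L)), nrow(gray), ncol(gray))
}

#' Gray-level co-occurrence matrix
#'
#' Counts pairs of quantized values at the given offset directions
#' (distance 1), optionally symmetrized by adding the transpose, and
#' normalizes to a probability matrix.
#'
#' @param gray integer matrix of quantized levels in \code{0..levels-1}
#' @param levels number of gray levels
#' @param angles subset of \code{c(0, 45, 90, 135)}
#' @param symmetric add the transposed counts before normalizing
#' @return named list of \linkS4class{CooccurrenceMatrix}, one per angle
#' @export
computeGlcm <- function(gray, levels, angles = c(0, 45, 90, 135),
                        symmetric = TRUE) {
  stopifnot(is.matrix(gray))
  levels <- as.integer(levels)
  if (any(gray < 0) || any(gray >= levels)) stop("grid values must be < levels")
  H <- nrow(gray); W <- ncol(gray)
  offs <- glcmOffsets()
  out <- list()
  for (a in as.character(angles)) {
    o <- offs[[a]]
    if (is.null(o)) stop("unsupported angle: ", a)
    r1 <- max(1L, 1L - o[1]):min(H, H - o[1])
    c1 <- max(1L, 1L - o[2]):min(W, W - o[2])
    if (!length(r1) || !length(c1))
      stop("image too small for a single pair at angle ", a)
    i <- gray[r1, c1, drop = FALSE]
    j <- gray[r1 + o[1], c1 + o[2], drop = FALSE]
    counts <- matrix(tabulate(as.vector(i) * levels + as.vector(j) + 1L,
                              nbins = levels * levels),
                     levels, levels, byrow = TRUE)
    if (symmetric) counts <- counts + t(counts)
    out[[a]] <- new("CooccurrenceMatrix", p = counts / sum(counts),
                    levels = levels, angle = as.numeric(a),
                    symmetric = symmetric)
  }
  out
}

#' Second-order texture statistics of a co-occurrence matrix
#'
#' Contrast, homogeneity, correlation, energy, dissimilarity and Shannon
#' entropy (bits, over nonzero cells) of a normalized GLCM, with 0-based
#' level indices i, j.  The homogeneity denominator defaults to the
#' \code{1 + (i+j)^2} form; \code{homogeneityForm = "standard"} switches to
#' the conventional \code{1 + (i-j)^2}.  A degenerate matrix with zero
#' marginal spread has correlation defined as 0.
#'
#' @param M a \linkS4class{CooccurrenceMatrix}, or a list of them (features
#'   are then averaged over the list, one value per statistic)
#' @param homogeneityForm \code{"printed"} (\code{1+(i+j)^2}) or
#'   \code{"standard"} (\code{1+(i-j)^2})
#' @return named numeric vector: contrast, homogeneity, correlation,
#'   energy, dissimilarity, entropy
#' @export
glcmFeatures <- function(M, homogeneityForm = c("printed", "standard")) {
  homogeneityForm <- match.arg(homogeneityForm)
  if (is.list(M)) {
    feats <- vapply(M, glcmFeatures, numeric(6),
                    homogeneityForm = homogeneityForm)
    return(rowMeans(feats))
  }
  stopifnot(is(M, "CooccurrenceMatrix"))
  p <- M@p
  n <- nrow(p)
  iIdx <- matrix(0:(n - 1), n, n)        # row index i
  jIdx <- t(iIdx)                        # col index j
  contrast <- sum((iIdx - jIdx)^2 * p)
  hden <- if (homogeneityForm == "printed") 1 + (iIdx + jIdx)^2
          else 1 + (iIdx - jIdx)^2
  homogeneity <- sum(p / hden)
  px <- rowSums(p); py <- colSums(p)
  lv <- 0:(n - 1)
  mx <- sum(lv * px); my <- sum(lv * py)
  sx <- sqrt(sum((lv - mx)^2 * px)); sy <- sqrt(sum((lv - my)^2 * py))
  correlation <- if (sx == 0 || sy == 0) 0 else
    sum(p * (iIdx - mx) * (jIdx - my)) / (sx * sy)
  energy <- sum(p^2)
  dissimilarity <- sum(abs(iIdx - jIdx) * p)
  nz <- p[p > 0]
  entropy <- -sum(nz * log2(nz))
  c(contrast = contrast, homogeneity = homogeneity,
    correlation = correlation, energy = energy,
    dissimilarity = dissimilarity, entropy = entropy)
}

#' Gray-level run-length matrices
#'
#' Counts maximal same-value runs along each scan direction: rows (0 deg),
#' anti-diagonals (45 deg), columns (90 deg) and main diagonals (135 deg).
#' Each direction's matrix records count(level, runLength), its
#' normalization, the mean gray level of the scanned pixels (1-based level
#' units, as used by the gray-level non-uniformity statistic) and the mean
#' run length of that direction's runs.
#'
#' @param gray integer matrix of quantized levels in \code{0..nGray-1}
#' @param nGray number of gray levels
#' @param angles subset of \code{c(0, 45, 90, 135)}
#' @return named list of \linkS4class{RunLengthMatrix}
#' @export
computeGlrlm <- function(gray, nGray, angles = c(0, 45, 90, 135)) {
  stopifnot(is.matrix(gray))
  nGray <- as.integer(nGray)
  if (any(gray < 0) || any(gray >= nGray)) stop("grid values must be < nGray")
  H <- nrow(gray); W <- ncol(gray)
  lineSets <- list(
    `0` = lapply(seq_len(H), function(r) gray[r, ]),
    `90` = lapply(seq_len(W), function(c) gray[, c]),
    `45` = lapply(seq(2, H + W), function(s) {    # bottom-left to top-right
      r <- seq(min(s - 1, H), max(1, s - W))
      gray[cbind(r, s - r)]
    }),
    `135` = lapply(seq(1 - W, H - 1), function(dlt) {  # top-left to bottom-right
      r <- seq(max(1, 1 + dlt), min(H, W + dlt))
      gray[cbind(r, r - dlt)]
    })
  )
  out <- list()
  for (a in as.character(angles)) {
    lines <- lineSets[[a]]
    if (is.null(lines)) stop("unsupported angle: ", a)
    lens <- integer(); vals <- integer()
    for (ln in lines) {
      r <- rle(as.integer(ln))
      lens <- c(lens, r$lengths); vals <- c(vals, r$values)
    }
    maxLen <- max(lens)
    counts <- matrix(tabulate(vals * maxLen + lens,
                              nbins = nGray * maxLen),
                     nGray, maxLen, byrow = TRUE)
    nPix <- sum(vapply(lines, length, integer(1)))
    out[[a]] <- new("RunLengthMatrix", counts = counts,
                    p = counts / sum(counts), nGray = nGray,
                    angle = as.numeric(a),
                    muG = mean(gray + 1),
                    muR = sum(lens) / length(lens),
                    nPixels = as.integer(nPix))
  }
  out
}

#' Run-length statistics (as-printed variant formulas)
#'
#' With 1-based gray-level index i and run length j and normalized run
#' probabilities p(i,j):
#' SRE = sum p(i,j) / (1 + (i+j)); LRE = sum p(i,j) / (1 + |i-j|);
#' GLN = sum p(i,j) (i - muG)^2 with muG the image's mean gray level;
#' RLN = sum p(i,j) (j - muR)^2 with muR the mean run length.
#' \code{formulas = "standard"} substitutes the classical Galloway
#' definitions (SRE = sum p/j^2, LRE = sum p j^2, GLN and RLN as squared
#' marginal sums divided by total runs, computed on raw counts).
#'
#' @param M a \linkS4class{RunLengthMatrix} or list of them (averaged)
#' @param formulas \code{"printed"} or \code{"standard"}
#' @return named numeric vector: SRE, LRE, GLN, RLN
#' @export
glrlmFeatures <- function(M, formulas = c("printed", "standard")) {
  formulas <- match.arg(formulas)
  if (is.list(M)) {
    feats <- vapply(M, glrlmFeatures, numeric(4), formulas = formulas)
    return(rowMeans(feats))
  }
  stopifnot(is(M, "RunLengthMatrix"))
  if (!sum(M@counts)) stop("empty run-length matrix")
  p <- M@p
  iIdx <- matrix(seq_len(nrow(p)), nrow(p), ncol(p))
  jIdx <- t(matrix(seq_len(ncol(p)), ncol(p), nrow(p)))
  if (formulas == "printed") {
    c(SRE = sum(p / (1 + (iIdx + jIdx))),
      LRE = sum(p / (1 + abs(iIdx - jIdx))),
      GLN = sum(p * (iIdx - M@muG)^2),
      RLN = sum(p * (jIdx - M@muR)^2))
  } else {
    cnt <- M@counts; nr <- sum(cnt)
    c(SRE = sum(cnt / jIdx^2) / nr,
      LRE = sum(cnt * jIdx^2) / nr,
      GLN = sum(rowSums(cnt)^2) / nr,
      RLN = sum(colSums(cnt)^2) / nr)
  }
}
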