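## circular neighbor sampling shared by the LBP and heterogeneity operators:
## P samples on a radius-R circle, bit p at angle 2*pi*p/P from the
## positive-x axis, proceeding counter-clockwise in image coordinates
## (column offset = R cos, row offset = -R sin), bilinearly interpolated.
## Returns a (Hin * Win) x P matrix of neighbor values for the interior
## pixels (margin ceiling(R) excluded on every side), plus the center values.
circularNeighborhood <- function(gray, P, R) {
  H <- nrow(gray); W <- ncol(gray)
  m <- ceiling(R)
  if (H < 2 * m + 1 || W < 2 * m + 1)
    stop("image smaller than the 2R+1 neighborhood")
  rs <- (m + 1):(H - m); cs <- (m + 1):(W - m)
  ctrR <- rep(rs, times = length(cs))
  ctrC <- rep(cs, each = length(rs))
  nb <- matrix(0, length(ctrR), P)
  for (p in seq_len(P) - 1L) {
    ang <- 2 * pi * p / P
    dc <- R * cos(ang); dr <- -R * sin(ang)
    # snap near-integer offsets so the 4 axial samples are exact
    if (abs(dc - round(dc)) < 1e-9) dc <- round(dc)
    if (abs(dr - round(dr)) < 1e-9) dr <- round(dr)
    nb[, p + 1L] <- bilinearSample(gray, ctrR + dr, ctrC + dc)
  }
  list(neighbors = nb, center = gray[cbind(ctrR, ctrC)],
       outDim = c(length(rs), length(cs)))
}

# rotation-invariant uniform (riu2) code table: a basic P-bit code with at
# most 2 circular 0/1 transitions maps to its popcount (0..P), all others
# to P+1
riu2Code <- function(bits) {
  P <- ncol(bits)
  trans <- rowSums(bits != bits[, c(2:P, 1), drop = FALSE])
  ones <- rowSums(bits)
  ifelse(trans <= 2, ones, P + 1L)
}

#' Local binary pattern map
#'
#' Thresholds P circularly-sampled neighbors at radius R against each
#' center pixel with s(x) = 1 iff x >= 0, and combines the bits as
#' \code{sum s(g_p - g_c) 2^p}.  Bit p corresponds to the neighbor at angle
#' \code{2 pi p / P} counter-clockwise from the positive-x axis;
#' non-integer sample positions are bilinearly interpolated.  Border pixels
#' (margin \code{ceiling(R)}) are excluded.  The \code{"riu2"} variant maps
#' uniform rotation classes to \code{0..P} and all non-uniform codes to
#' \code{P+1}.
#'
#' @param gray numeric matrix of intensities
#' @param P number of neighbors (basic variant requires P <= 24)
#' @param R radius in pixels (>= 1)
#' @param variant \code{"basic"} or \code{"riu2"}
#' @return an \linkS4class{LBPMap}
#' @export
lbpMap <- function(gray, P = 8L, R = 1, variant = c("basic", "riu2")) {
  variant <- match.arg(variant)
  P <- as.integer(P)
  if (R < 1) stop("R must be >= 1")
  cn <- circularNeighborhood(gray, P, R)
  # tolerance absorbs bilinear round-off so s(0) = 1 holds exactly on
  # constant neighborhoods (intensities are integer-scaled)
  bits <- (cn$neighbors >= cn$center - 1e-7) * 1L
  codes <- if (variant == "basic") {
    if (P > 24L) stop("basic variant limited to P <= 24")
    as.integer(bits %*% 2^(seq_len(P) - 1))
  } else as.integer(riu2Code(bits))
  new("LBPMap", codes = matrix(codes, cn$outDim[1], cn$outDim[2]),
      P = P, R = as.numeric(R), variant = variant)
}

#' Convert an LBP binary string to its decimal code
#'
#' Interprets the string with the most significant bit first, as in the
#' usual presentation of a thresholded 3x3 neighborhood read around the
#' center (e.g. "11001001" -> 201).
#'
#' @param bits a character string of 0/1
#' @return integer code
#' @export
lbpStringToDecimal <- function(bits) {
  b <- as.integer(strsplit(bits, "")[[1]])
  if (anyNA(b) || any(!b %in% 0:1)) stop("bits must be a 0/1 string")
  sum(b * 2^(rev(seq_along(b)) - 1))
}

#' Multi-resolution riu2 LBP histogram features
#'
#' For each (P, R) configuration, the normalized histogram of riu2 codes
#' (length P + 2), concatenated in the given order.  Default configurations
#' (8,1), (16,2), (24,3) give a 54-element descriptor.
#'
#' @param gray numeric matrix of intensities
#' @param configs list of c(P, R) pairs
#' @return named numeric vector; each block sums to 1
#' @export
lbpHistogramFeatures <- function(gray,
                                 configs = list(c(8, 1), c(16, 2), c(24, 3))) {
  out <- numeric()
  for (cfg in configs) {
    P <- as.integer(cfg[1]); R <- cfg[2]
    map <- lbpMap(gray, P, R, variant = "riu2")
    h <- tabulate(as.vector(map@codes) + 1L, nbins = P + 2L)
    h <- h / sum(h)
    names(h) <- sprintf("p%dr%g.bin%d", P, R, seq_len(P + 2L) - 1L)
    out <- c(out, h)
  }
  out
}

#' Per-pixel heterogeneity maps
#'
#' For the same circular neighborhood geometry as \code{\link{lbpMap}}:
#' the variance map V = (1/P) sum (g_i - mu)^2 over the P sampled
#' neighbors, and the homogeneity map
#' H = 1 - (1/L) sqrt(sum (w_i - m)^2) with m the neighborhood median and
#' L = P the neighborhood size.  V >= 0 everywhere; H = 1 on constant
#' neighborhoods.
#'
#' @param gray numeric matrix of intensities
#' @param P,R neighborhood geometry
#' @return a \linkS4class{HeterogeneityMaps}
#' @export
heterogeneityMaps <- function(gray, P = 8L, R = 1) {
  P <- as.integer(P)
  cn <- circularNeighborhood(gray, P, R)
  nb <- cn$neighbors
  mu <- rowMeans(nb)
  V <- rowMeans((nb - mu)^2)
  med <- apply(nb, 1L, stats::median)
  H <- 1 - sqrt(rowSums((nb - med)^2)) / P
  # interpolation round-off floor: constant neighborhoods are exactly
  # V = 0, H = 1
  V[V < 1e-16] <- 0
  H[H > 1 - 1e-12] <- 1
  new("HeterogeneityMaps",
      varianceMap = matrix(V, cn$outDim[1], cn$outDim[2]),
      homogeneityMap = matrix(H, cn$outDim[1], cn$outDim[2]),
      P = P, R = as.numeric(R))
}

#' Heterogeneity-weighted LBP histogram
#'
#' Accumulates each pixel's heterogeneity weight — the local variance V
#' (\code{mode = "variance"}) or local dissimilarity 1 - H
#' (\code{mode = "dissimilarity"}) — into its LBP code's bin, then
#' normalizes to sum 1.  A zero total weight (e.g. a constant image in
#' variance mode) yields the all-zero vector.
#'
#' @param map an \linkS4class{LBPMap}
#' @param het a \linkS4class{HeterogeneityMaps} aligned with \code{map}
#' @param mode \code{"variance"} or \code{"dissimilarity"}
#' @return numeric vector of length \code{P+2} (riu2) or \code{2^P} (basic)
#' @export
heterogeneityWeightedLbp <- function(map, het,
                                     mode = c("variance", "dissimilarity")) {
  mode <- match.arg(mode)
  stopifnot(is(map, "LBPMap"), is(het, "HeterogeneityMaps"))
  w <- if (mode == "variance") het@varianceMap else 1 - het@homogeneityMap
  if (!identical(dim(w), dim(map@codes)))
    stop("LBP map and heterogeneity map shapes differ")
  nbins <- if (map@variant == "riu2") map@P + 2L else 2L^map@P
  h <- vapply(seq_len(nbins) - 1L,
              function(code) sum(w[map@codes == code]), numeric(1))
  tot <- sum(h)
  if (tot > 0) h <- h / tot
  names(h) <- sprintf("bin%d", seq_len(nbins) - 1L)
  h
}

#' Gaussian image pyramid
#'
#' Level 1 is the input; each further level is the previous one smoothed
#' with an isotropic Gaussian (sigma = 1) and downsampled by keeping every
#' second row and column, so sizes halve (floor) per level.
#'
#' @param gray numeric matrix
#' @param nLevels number of levels (>= 1); the base image must be at least
#'   \code{2^(nLevels-1) * 16} pixels per side
#' @return list of matrices, coarsest last
#' @export
imagePyramid <- function(gray, nLevels = 3L) {
  stopifnot(is.matrix(gray))
  nLevels <- as.integer(nLevels)
  if (nLevels < 1L) stop("nLevels must be >= 1")
  if (min(dim(gray)) < 2^(nLevels - 1L) * 16)
    stop("image too small for ", nLevels, " pyramid levels")
  out <- vector("list", nLevels)
  out[[1]] <- gray
  for (lv in seq_len(nLevels - 1L)) {
    prev <- out[[lv]]
    sm <- t(as.matrix(EBImage::gblur(EBImage::Image(t(prev)), sigma = 1)))
    out[[lv + 1L]] <- sm[seq_len(nrow(sm) %/% 2L) * 2L - 1L,
                         seq_len(ncol(sm) %/% 2L) * 2L - 1L, drop = FALSE]
  }
  out
}

#' GLCM statistics of the LBP-coded image (LBGLCM)
#'
#' Applies the basic LBP operator, re-quantizes the \code{2^P} code range
#' down to \code{levels} gray levels, and extracts the six co-occurrence
#' statistics (averaged over the four directions) from the LBP image.
#'
#' @param gray numeric matrix of intensities
#' @param P,R LBP geometry
#' @param levels co-occurrence quantization of the code range (default 64)
#' @param ... passed to \code{\link{glcmFeatures}}
#' @return named numeric vector of the six GLCM statistics
#' @export
lbglcmFeatures <- function(gray, P = 8L, R = 1, levels = 64L, ...) {
  map <- lbpMap(gray, P, R, variant = "basic")
  q <- matrix(as.integer(floor(map@codes * levels / 2^map@P)),
              nrow(map@codes), ncol(map@codes))
  q <- pmin(q, as.integer(levels) - 1L)
  glcmFeatures(computeGlcm(q, levels = levels), ...)
}

#' Multi-scale pyramid LBGLCM descriptor
#'
#' Computes the LBGLCM statistics at every level of a Gaussian pyramid and
#' concatenates the per-level blocks (level 1 first).  Co-occurrence
#' quantization is 128 levels at the base scale and 64 at coarser scales by
#' default.  When \code{stats} (a list with \code{min} and \code{max}
#' vectors, as fit on training data) is supplied, each element is min-max
#' scaled with those frozen statistics; otherwise raw statistics are
#' returned (the pipeline scales all feature blocks with training-fold
#' statistics at fusion time).
#'
#' @param gray numeric matrix of intensities
#' @param nLevels pyramid depth (default 3)
#' @param P,R LBP geometry per scale
#' @param levels integer vector of co-occurrence quantization per level
#'   (recycled)
#' @param stats optional frozen min-max normalization statistics
#' @return named numeric vector of length \code{6 * nLevels}
#' @export
multiscaleLbglcm <- function(gray, nLevels = 3L, P = 8L, R = 1,
                             levels = c(128L, 64L, 64L), stats = NULL) {
  pyr <- imagePyramid(gray, nLevels)
  levels <- rep(levels, length.out = nLevels)
  out <- numeric()
  for (lv in seq_len(nLevels)) {
    f <- lbglcmFeatures(pyr[[lv]], P = P, R = R, levels = levels[lv])
    names(f) <- sprintf("l%d.%s", lv - 1L, names(f))
    out <- c(out, f)
  }
  if (!is.null(stats)) {
    rng <- pmax(stats$max - stats$min, .Machine$double.eps)
    out <- pmin(pmax((out - stats$min) / rng, 0), 1)
  }
  out
}
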