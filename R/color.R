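#' Per-channel color histograms
#'
#' Uniform-bin histograms of the R, G, B channels; counts sum to the pixel
#' count in every channel.
#'
#' @param image an RGB 8-bit \linkS4class{RasterImage}
#' @param bins number of uniform bins (>= 2)
#' @return named list of integer vectors \code{R}, \code{G}, \code{B}
#' @export
colorHistogram <- function(image, bins = 8L) {
  stopifnot(is(image, "RasterImage"))
  if (nChannels(image) != 3L) stop("colorHistogram requires an RGB image")
  bins <- as.integer(bins)
  if (bins < 2L) stop("bins must be >= 2")
  px <- image@pixels
  mx <- 2^image@bitDepth
  lapply(stats::setNames(1:3, c("R", "G", "B")), function(ch) {
    idx <- pmin(floor(px[, , ch] * bins / mx), bins - 1L) + 1L
    tabulate(idx, nbins = bins)
  })
}

# root-moment summary of one numeric channel: the mean, the 1/N rms
# deviation, its square, the signed cube root of the third central moment
# mean and the fourth root of the fourth central moment mean
rootMoments <- function(v, standardized = FALSE) {
  mu <- mean(v)
  d <- v - mu
  m2 <- mean(d^2); m3 <- mean(d^3); m4 <- mean(d^4)
  sd <- sqrt(m2)
  if (standardized) {
    skew <- if (sd > 0) m3 / sd^3 else 0
    kurt <- if (sd > 0) m4 / sd^4 else 0
  } else {
    skew <- sign(m3) * abs(m3)^(1 / 3)
    kurt <- m4^(1 / 4)
  }
  c(mean = mu, std = sd, var = m2, skew = skew, kurt = kurt)
}

#' Pixel-based color moments (RGB channels)
#'
#' Per channel: mean, standard deviation (1/N root-mean-square deviation),
#' variance, skewness and kurtosis.  Skewness and kurtosis default to the
#' root-moment forms — the signed cube root of the mean cubed deviation and
#' the fourth root of the mean fourth-power deviation;
#' \code{moments = "standardized"} switches to the conventional
#' standardized moments m3/sd^3 and m4/sd^4.
#'
#' @param image an RGB \linkS4class{RasterImage}
#' @param moments \code{"root"} or \code{"standardized"}
#' @return named numeric vector \code{cm.{R,G,B}.{mean,std,var,skew,kurt}}
#' @export
colorMoments <- function(image, moments = c("root", "standardized")) {
  moments <- match.arg(moments)
  stopifnot(is(image, "RasterImage"))
  if (nChannels(image) != 3L) stop("colorMoments requires an RGB image")
  out <- numeric()
  for (ch in 1:3) {
    m <- rootMoments(as.vector(image@pixels[, , ch]),
                     standardized = moments == "standardized")
    names(m) <- sprintf("cm.%s.%s", c("R", "G", "B")[ch], names(m))
    out <- c(out, m)
  }
  out
}

#' Color moments of the HSV hue and saturation channels
#'
#' Converts to HSV (H in [0, 360), S in [0, 1]) and summarizes the H and S
#' channels with the same moment set as \code{\link{colorMoments}}.  The
#' value channel is excluded: it carries the illumination component that
#' the HSV representation is used to discount.
#'
#' @inheritParams colorMoments
#' @return named numeric vector \code{cm.{H,S}.{mean,std,var,skew,kurt}}
#' @export
hsvMoments <- function(image, moments = c("root", "standardized")) {
  moments <- match.arg(moments)
  stopifnot(is(image, "RasterImage"))
  if (nChannels(image) != 3L) stop("hsvMoments requires an RGB image")
  px <- image@pixels
  mx <- 2^image@bitDepth - 1
  hsv <- grDevices::rgb2hsv(r = as.vector(px[, , 1]),
                            g = as.vector(px[, , 2]),
                            b = as.vector(px[, , 3]), maxColorValue = mx)
  out <- numeric()
  for (ch in c(H = 1L, S = 2L)) {
    v <- hsv[ch, ]
    if (ch == 1L) v <- v * 360
    m <- rootMoments(v, standardized = moments == "standardized")
    names(m) <- sprintf("cm.%s.%s", c("H", "S")[ch], names(m))
    out <- c(out, m)
  }
  out
}

#' Quantize an RGB image into a single shade channel
#'
#' With \code{shades = a^3}, each channel is binned into \code{a} uniform
#' bins (\code{qC = floor(C a / 256)}) and combined as
#' \code{qR a^2 + qG a + qB}, giving shade indices \code{0..shades-1}.
#'
#' @param image an RGB 8-bit \linkS4class{RasterImage}
#' @param shades number of shades; must be a perfect cube (default 64)
#' @return integer matrix of shade indices
#' @export
quantizeColors <- function(image, shades = 64L) {
  stopifnot(is(image, "RasterImage"))
  if (nChannels(image) != 3L) stop("quantizeColors requires an RGB image")
  a <- round(shades^(1 / 3))
  if (a^3 != shades) stop("shades must be a perfect cube")
  px <- image@pixels
  mx <- 2^image@bitDepth
  q <- function(ch) pmin(floor(px[, , ch] * a / mx), a - 1)
  matrix(as.integer(q(1) * a^2 + q(2) * a + q(3)), nrow(px), ncol(px))
}

#' Rotation- and scale-invariant hybrid color-texture descriptor (RSHD)
#'
#' Quantizes the RGB space into 64 shades; for each shade, slides a 2x2
#' window over the shade's binary occupancy map and classifies every
#' window into one of 5 rotation-invariant structure classes by its count
#' of set pixels (0..4; the 2-count class merges the diagonal and adjacent
#' pair arrangements, making every class invariant under quarter-turn
#' rotations).  The 64 x 5 count grid is L1-normalized into a 320-element
#' descriptor.
#'
#' @param image an RGB 8-bit \linkS4class{RasterImage}, at least 2x2
#' @param shades number of quantized shades (perfect cube, default 64)
#' @return named numeric vector of length \code{shades * 5}, summing to 1
#' @export
rshd <- function(image, shades = 64L) {
  stopifnot(is(image, "RasterImage"))
  d <- dim(image@pixels)
  if (d[1] < 2 || d[2] < 2) stop("rshd requires at least a 2x2 image")
  sm <- quantizeColors(image, shades)
  H <- nrow(sm); W <- ncol(sm)
  counts <- matrix(0, shades, 5L)
  for (s in seq_len(shades) - 1L) {
    B <- (sm == s) * 1L
    wc <- B[-H, -W] + B[-H, -1] + B[-1, -W] + B[-1, -1]
    counts[s + 1L, ] <- tabulate(wc + 1L, nbins = 5L)
  }
  v <- as.vector(t(counts))          # shade-major: s0.e0..e4, s1.e0..
  v <- v / sum(v)
  names(v) <- sprintf("s%d.e%d", rep(seq_len(shades) - 1L, each = 5L),
                      rep(0:4, shades))
  v
}
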