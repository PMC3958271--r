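## Four-directional even-symmetric Gabor filtering. Veins are dark
## curvilinear structures; an even (cosine-phase) Gabor kernel aligned with
## a vein produces a strongly negative response at its center, so taking the
## per-pixel minimum over the four orientation channels keeps the darkest
## (best aligned) response everywhere.

#' Gabor filter bank parameters
#'
#' Defaults follow the vein-imaging setting: center frequency
#' \code{f = 0.05} cycles/pixel (20-pixel wavelength, matching vein widths
#' of a few to ten pixels), isotropic envelope
#' \code{sigmaX = sigmaY = 9.53}, and the four orientations
#' \code{theta = i * pi / 4}, i = 1..4. The kernel side defaults to the
#' largest odd size not exceeding 6 sigma (57 for sigma 9.53).
#'
#' @param f spatial center frequency in cycles/pixel.
#' @param sigmaX,sigmaY Gaussian envelope scales in pixels.
#' @param orientations angles in radians.
#' @param kernelSize odd kernel side in pixels, or NULL for the default.
#' @return validated list of parameters.
#' @export
gaborParams <- function(f = 0.05, sigmaX = 9.53, sigmaY = 9.53,
                        orientations = (1:4) * pi / 4, kernelSize = NULL) {
  if (f <= 0 || sigmaX <= 0 || sigmaY <= 0)
    stop("gaborParams: f, sigmaX and sigmaY must be positive")
  if (is.null(kernelSize)) {
    kernelSize <- floor(6 * max(sigmaX, sigmaY))
    if (kernelSize %% 2L == 0L) kernelSize <- kernelSize - 1L
    kernelSize <- max(kernelSize, 3L)
  }
  if (kernelSize %% 2L == 0L || kernelSize < 3L)
    stop("gaborParams: kernelSize must be odd and >= 3")
  list(f = f, sigmaX = sigmaX, sigmaY = sigmaY,
       orientations = orientations, kernelSize = as.integer(kernelSize))
}

#' Even-symmetric Gabor kernel
#'
#' \deqn{G(x, y) = \frac{1}{2\pi\sigma_x\sigma_y}
#'   \exp\{-\tfrac12(x_\theta^2/\sigma_x^2 + y_\theta^2/\sigma_y^2)\}
#'   \cos(2\pi f x_\theta)}
#' with rotated coordinates \eqn{x_\theta = x\cos\theta + y\sin\theta},
#' \eqn{y_\theta = -x\sin\theta + y\cos\theta}, centered on the kernel
#' midpoint. When \code{zeroMean = TRUE} (the default used by the bank) the
#' kernel mean is subtracted so flat regions map to zero response.
#'
#' @param p parameters from \code{\link{gaborParams}}.
#' @param theta orientation in radians.
#' @param zeroMean subtract the kernel mean (zero DC response).
#' @return square numeric matrix of side \code{p$kernelSize}.
#' @export
gaborKernel <- function(p = gaborParams(), theta = 0, zeroMean = FALSE) {
  n <- p$kernelSize
  r <- (n - 1L) %/% 2L
  d <- seq.int(-r, r)
  x <- matrix(d, n, n, byrow = TRUE)   # column offset
  y <- matrix(d, n, n)                 # row offset, downwards
  xt <- x * cos(theta) + y * sin(theta)
  yt <- -x * sin(theta) + y * cos(theta)
  k <- (1 / (2 * pi * p$sigmaX * p$sigmaY)) *
    exp(-0.5 * (xt^2 / p$sigmaX^2 + yt^2 / p$sigmaY^2)) *
    cos(2 * pi * p$f * xt)
  if (zeroMean) k <- k - mean(k)
  k
}

#' Four-directional Gabor filtering with min-combination
#'
#' Convolves the image with one zero-mean even-symmetric Gabor kernel per
#' orientation and keeps, at every pixel, the lowest response over the
#' channels: the vein line is darker than the skin, so the aligned channel's
#' response is the most negative one. The combined response is min-max
#' rescaled back to [0, 255], leaving skin near mid-gray and veins dark.
#'
#' @param img numeric matrix in [0, 255].
#' @param p parameters from \code{\link{gaborParams}}.
#' @param rescale rescale output to [0, 255] (disable to inspect the raw
#'   min-combined response).
#' @return numeric matrix, same shape as \code{img}.
#' @export
applyGaborBank <- function(img, p = gaborParams(), rescale = TRUE) {
  img <- grayImage(img)
  combined <- NULL
  for (theta in p$orientations) {
    k <- gaborKernel(p, theta, zeroMean = TRUE)
    o <- convolve2d(img, k)
    combined <- if (is.null(combined)) o else pmin(combined, o)
  }
  if (rescale) rescaleMinMax(combined, 0, 255) else combined
}
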