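## Single-scale Retinex: the image is modeled as illumination times
## reflectance; the illumination is estimated as a Gaussian-smoothed
## surround and divided out in the log domain, which removes smooth
## illumination gradients and raises the global contrast of the vein lines.

#' Single-scale Retinex parameters
#'
#' @param sigma Gaussian surround scale in pixels. The presets studied for
#'   vein images are 10, 15, 20, 25 and 50; larger sigma smooths the
#'   illumination estimate more, reducing amplified noise in skin regions.
#'   Default 20.
#' @param epsilon positive offset added before both logarithms to guard
#'   log(0) on the 8-bit scale; default 1.
#' @return validated list of parameters.
#' @export
retinexParams <- function(sigma = 20, epsilon = 1) {
  if (sigma <= 0) stop("retinexParams: sigma must be positive")
  if (epsilon <= 0) stop("retinexParams: epsilon must be positive")
  list(sigma = sigma, epsilon = epsilon)
}

#' Single-scale Retinex enhancement
#'
#' Computes \eqn{\log r = \log(L + \epsilon) - \log(G_\sigma * L + \epsilon)}
#' where \eqn{G_\sigma} is a unit-sum Gaussian truncated at 3 sigma
#' (reflect padding). In the small-epsilon limit the output is invariant to
#' global multiplicative illumination. The log-ratio is min-max rescaled to
#' [0, 255] for display and downstream fusion.
#'
#' @param img numeric matrix in [0, 255].
#' @param p parameters from \code{\link{retinexParams}}.
#' @param rescale rescale output to [0, 255]; disable to obtain the raw
#'   log-ratio.
#' @return numeric matrix, same shape as \code{img}.
#' @export
ssr <- function(img, p = retinexParams(), rescale = TRUE) {
  img <- grayImage(img)
  g <- gaussianKernel(p$sigma)
  surround <- convolve2d(img, g)
  logr <- log(img + p$epsilon) - log(surround + p$epsilon)
  if (rescale) rescaleMinMax(logr, 0, 255) else logr
}
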