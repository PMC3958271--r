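## Finger-region detection. The finger appears bright against a dark
## background, so the upper boundary is a dark-to-bright transition going
## down the image and the lower boundary the reverse. Each boundary is found
## per column by template matching with a 20 x 4 edge mask whose rows sum
## to zero.

#' Boundary detection mask
#'
#' A \code{maskH x maskW} edge template. The upper mask has -1 on its top
#' half and +1 on its bottom half (dark background above, bright finger
#' below); the lower mask is the vertical mirror. Entries sum to zero, so
#' the response is a pure edge detector.
#'
#' @param polarity \code{"upper"} or \code{"lower"}.
#' @param maskW,maskH template width and height in pixels (defaults 20 x 4).
#' @return numeric matrix of dimension \code{maskH x maskW}.
#' @export
boundaryMask <- function(polarity = c("upper", "lower"), maskW = 20L,
                         maskH = 4L) {
  polarity <- match.arg(polarity)
  if (maskH %% 2L != 0L) stop("mask height must be even")
  half <- maskH %/% 2L
  m <- rbind(matrix(-1, half, maskW), matrix(1, half, maskW))
  if (polarity == "lower") m <- m[rev(seq_len(maskH)), , drop = FALSE]
  m
}

# Block sums over an integral image; rows r1..r2, cols c1..c2 (1-based).
blockSum <- function(S, r1, r2, c1, c2) {
  S[r2 + 1L, c2 + 1L] - S[r1, c2 + 1L] - S[r2 + 1L, c1] + S[r1, c1]
}

#' Detect upper and lower finger boundaries
#'
#' For every column, the boundary row is the one maximizing the template
#' response, searched in the top half of the image for the upper boundary
#' and the bottom half for the lower. Responses are computed only where the
#' mask fits entirely inside the image; edge columns inherit the nearest
#' valid column's boundary. Ties go to the smallest row. \code{upperY} is
#' the first finger row, \code{lowerY} the last.
#'
#' @param img numeric matrix in [0, 255].
#' @param maskW,maskH template size (defaults 20 x 4).
#' @param x1,x2 horizontal crop limits stored in the result (see
#'   \code{\link{cropRoi}}); defaults 0.
#' @return a \linkS4class{FingerROI}. The \code{degenerate} flag is set when
#'   neither mask sees any edge signal (all responses equal).
#' @export
detectBoundaries <- function(img, maskW = 20L, maskH = 4L, x1 = 0L, x2 = 0L) {
  img <- grayImage(img)
  h <- nrow(img); w <- ncol(img)
  if (w < maskW)
    stop("detectBoundaries: image narrower than the mask width")
  if (h < 2L * maskH)
    stop("detectBoundaries: image must be at least twice the mask height")
  half <- maskH %/% 2L

  # integral image with a zero border
  S <- matrix(0, h + 1L, w + 1L)
  S[-1L, -1L] <- apply(apply(img, 2L, cumsum), 1L, cumsum) |> t()

  cl <- maskW %/% 2L - 1L              # columns left of center (9 for w=20)
  cr <- maskW - cl - 1L                # columns right of center (10)
  xs <- seq.int(cl + 1L, w - cr)       # columns where the mask fits

  # upper boundary: y = first finger row; mask rows (y-half)..(y+half-1)
  yUp <- seq.int(half + 1L, max(half + 1L, h %/% 2L))
  # lower boundary: y = last finger row; mask rows (y-half+1)..(y+half)
  yLo <- seq.int(h %/% 2L + 1L, h - half)

  respUp <- matrix(0, length(yUp), length(xs))
  respLo <- matrix(0, length(yLo), length(xs))
  for (i in seq_along(yUp)) {
    y <- yUp[i]
    respUp[i, ] <- blockSum(S, y, y + half - 1L, xs - cl, xs + cr) -
      blockSum(S, y - half, y - 1L, xs - cl, xs + cr)
  }
  for (i in seq_along(yLo)) {
    y <- yLo[i]
    respLo[i, ] <- blockSum(S, y - half + 1L, y, xs - cl, xs + cr) -
      blockSum(S, y + 1L, y + half, xs - cl, xs + cr)
  }

  upper <- yUp[apply(respUp, 2L, which.max)]
  lower <- yLo[apply(respLo, 2L, which.max)]
  degenerate <- diff(range(respUp)) == 0 && diff(range(respLo)) == 0

  # extend to edge columns where the mask did not fit
  upperFull <- rep(NA_integer_, w); lowerFull <- rep(NA_integer_, w)
  upperFull[xs] <- upper; lowerFull[xs] <- lower
  upperFull[seq_len(xs[1] - 1L)] <- upper[1L]
  lowerFull[seq_len(xs[1] - 1L)] <- lower[1L]
  if (xs[length(xs)] < w) {
    tail <- seq.int(xs[length(xs)] + 1L, w)
    upperFull[tail] <- upper[length(upper)]
    lowerFull[tail] <- lower[length(lower)]
  }

  new("FingerROI", upperY = as.integer(upperFull),
      lowerY = as.integer(lowerFull), x1 = as.integer(x1),
      x2 = as.integer(x2), degenerate = degenerate)
}

#' Crop the finger region of interest
#'
#' Retains columns \code{(x1 + 1) .. (width - x2)} and rows between the
#' extreme boundary positions. The \code{database_I} profile uses the
#' 640-pixel-wide convention x1 = 220, x2 = 169; \code{database_II} the
#' 320-pixel convention x1 = 20, x2 = 51. A vertical inset removes extra
#' rows top and bottom: the silhouette transition sits on the detected
#' boundary rows, is noisy on low-resolution captures, and dominates any
#' band-pass filter response, so trimming it keeps the enhancement
#' statistics about veins rather than the finger outline. By default the
#' inset is 4 rows for \code{database_II} and 0 otherwise.
#'
#' @param img numeric matrix in [0, 255].
#' @param roi a \linkS4class{FingerROI} for \code{img}.
#' @param profile \code{"custom"}, \code{"database_I"} or \code{"database_II"}.
#' @param verticalInset extra rows removed top and bottom (applies to every
#'   profile when given).
#' @return list with \code{image} (the cropped matrix) and \code{roi}
#'   (boundaries re-expressed in cropped coordinates, x1 = x2 = 0).
#' @export
cropRoi <- function(img, roi, profile = c("custom", "database_I",
                                          "database_II"),
                    verticalInset = NULL) {
  img <- grayImage(img)
  profile <- match.arg(profile)
  if (is.null(verticalInset))
    verticalInset <- if (profile == "database_II") 4L else 0L
  w <- ncol(img)
  lim <- switch(profile,
    custom = c(roi@x1, roi@x2),
    database_I = c(220L, 169L),
    database_II = c(20L, 51L))
  x1 <- lim[1]; x2 <- lim[2]
  if (x1 + x2 >= w) stop("cropRoi: degenerate ROI, no columns retained")
  cols <- seq.int(x1 + 1L, w - x2)
  up <- roi@upperY[cols]; lo <- roi@lowerY[cols]
  r1 <- min(up) + as.integer(verticalInset)
  r2 <- max(lo) - as.integer(verticalInset)
  if (r2 <= r1) stop("cropRoi: degenerate ROI, no rows retained")
  out <- img[seq.int(r1, r2), cols, drop = FALSE]
  newUp <- pmax(up - r1 + 1L, 1L)
  newLo <- pmin(lo - r1 + 1L, nrow(out))
  # boundary noise can locally invert the pair; clamp to keep the ROI valid
  newLo <- pmax(newLo, 2L)
  newUp <- pmin(newUp, newLo - 1L)
  newRoi <- new("FingerROI", upperY = as.integer(newUp),
                lowerY = as.integer(newLo), x1 = 0L, x2 = 0L,
                degenerate = roi@degenerate)
  list(image = out, roi = newRoi)
}
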