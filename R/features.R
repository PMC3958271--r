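## Feature extraction: boundary-based size normalization to 150 x 60,
## 3 x 3 block-mean downsampling to 50 x 20, then either 6,912-bit LBP
## codes matched by Hamming distance or 128 wavelet-packet statistics
## matched by (root-mean-square) Euclidean distance.

NORM_WIDTH <- 150L
NORM_HEIGHT <- 60L
DOWN_WIDTH <- 50L
DOWN_HEIGHT <- 20L

#' Boundary-based size normalization
#'
#' Linearly stretches the finger region to a fixed 150 x 60 rectangle:
#' each retained column's span between its upper and lower boundary rows is
#' resampled to 60 rows by linear interpolation, then each row is resampled
#' to 150 columns. This equalizes finger shape and straightens the vein
#' field before code extraction.
#'
#' @param img numeric matrix in [0, 255].
#' @param roi a \linkS4class{FingerROI} in the coordinates of \code{img}.
#' @return 60 x 150 numeric matrix.
#' @export
normalizeSize <- function(img, roi) {
  img <- grayImage(img)
  w <- ncol(img)
  if (length(roi@upperY) != w)
    stop("normalizeSize: roi does not match the image width")
  cols <- seq.int(roi@x1 + 1L, w - roi@x2)
  if (length(cols) < 2L) stop("normalizeSize: degenerate ROI")
  stretched <- matrix(0, NORM_HEIGHT, length(cols))
  for (j in seq_along(cols)) {
    x <- cols[j]
    y1 <- roi@upperY[x]; y2 <- roi@lowerY[x]
    if (y2 <= y1) stop("normalizeSize: degenerate ROI at column ", x)
    src <- seq.int(y1, y2)
    at <- seq(y1, y2, length.out = NORM_HEIGHT)
    stretched[, j] <- stats::approx(src, img[src, x], xout = at)$y
  }
  out <- matrix(0, NORM_HEIGHT, NORM_WIDTH)
  srcX <- seq_along(cols)
  atX <- seq(1, length(cols), length.out = NORM_WIDTH)
  for (i in seq_len(NORM_HEIGHT))
    out[i, ] <- if (length(cols) == NORM_WIDTH) stretched[i, ]
                else stats::approx(srcX, stretched[i, ], xout = atX)$y
  out
}

#' 3 x 3 block-mean downsampling
#'
#' @param img 60 x 150 numeric matrix (the normalized vein image).
#' @return 20 x 50 numeric matrix of block means.
#' @export
downsample3x3 <- function(img) {
  if (nrow(img) != NORM_HEIGHT || ncol(img) != NORM_WIDTH)
    stop(sprintf("downsample3x3: input must be %d x %d",
                 NORM_HEIGHT, NORM_WIDTH))
  ri <- (seq_len(NORM_HEIGHT) - 1L) %/% 3L + 1L
  ci <- (seq_len(NORM_WIDTH) - 1L) %/% 3L + 1L
  sums <- rowsum(t(rowsum(img, ri)), ci)
  out <- t(sums) / 9
  dimnames(out) <- NULL
  out
}

#' 6,912-bit LBP vein code
#'
#' For each of the 48 x 18 interior pixels of the 50 x 20 image, eight bits
#' compare the eight neighbors to the center (neighbor >= center gives 1)
#' in clockwise order starting at the top-left neighbor; codes are
#' concatenated row-major.
#'
#' @param img 20 x 50 numeric matrix.
#' @return a \linkS4class{VeinCode} of 6,912 bits.
#' @export
lbpCode <- function(img) {
  if (nrow(img) != DOWN_HEIGHT || ncol(img) != DOWN_WIDTH)
    stop(sprintf("lbpCode: input must be %d x %d", DOWN_HEIGHT, DOWN_WIDTH))
  h <- DOWN_HEIGHT; w <- DOWN_WIDTH
  ctr <- img[2:(h - 1L), 2:(w - 1L)]
  # clockwise from the top-left neighbor
  offs <- list(c(-1L, -1L), c(-1L, 0L), c(-1L, 1L), c(0L, 1L),
               c(1L, 1L), c(1L, 0L), c(1L, -1L), c(0L, -1L))
  nb <- lapply(offs, function(o)
    img[2:(h - 1L) + o[1], 2:(w - 1L) + o[2]])
  # bits per pixel in order, pixels row-major
  bits <- integer(8L * (h - 2L) * (w - 2L))
  pos <- 0L
  for (i in seq_len(h - 2L)) {
    for (j in seq_len(w - 2L)) {
      for (b in 1:8) {
        pos <- pos + 1L
        bits[pos] <- as.integer(nb[[b]][i, j] >= ctr[i, j])
      }
    }
  }
  new("VeinCode", bits = bits, width = w - 2L, height = h - 2L,
      bitsPerPixel = 8L)
}

#' Normalized Hamming distance between vein codes
#'
#' Fraction of differing bits: \eqn{HD = popcount(a \oplus b) / N} with
#' N the code length (6,912).
#'
#' @param a,b \linkS4class{VeinCode} objects of equal length.
#' @return distance in [0, 1].
#' @export
hammingDistance <- function(a, b) {
  if (length(a@bits) != length(b@bits))
    stop("hammingDistance: code lengths differ")
  mean(a@bits != b@bits)
}

#' Wavelet-packet mean/STD features
#'
#' Three-level full wavelet-packet decomposition (64 terminal sub-bands)
#' with Haar or Daubechies (db2) filters; the mean and population STD of
#' the coefficients in each sub-band give 128 features. By default the
#' vector is min-max normalized to [0, 1]; for gallery evaluation the
#' normalization is instead applied per feature across the enrolled set
#' (see \code{\link{normalizeFeatureMatrix}}).
#'
#' @param img 20 x 50 numeric matrix.
#' @param basis \code{"haar"} or \code{"daubechies"}.
#' @param normalize min-max normalize the returned vector.
#' @return numeric vector of length 128 (mean, STD per sub-band, in the
#'   canonical packet order).
#' @export
waveletFeatures <- function(img, basis = c("haar", "daubechies"),
                            normalize = TRUE) {
  basis <- match.arg(basis)
  bands <- waveletPacket(img, basis, levels = 3L)
  feats <- unlist(lapply(bands, function(b) {
    v <- as.numeric(b)
    c(mean(v), sqrt(mean((v - mean(v))^2)))
  }))
  if (normalize) feats <- rescaleFeatureVector(feats)
  feats
}

rescaleFeatureVector <- function(v) {
  rng <- range(v)
  if (diff(rng) <= 0) return(rep(0.5, length(v)))
  (v - rng[1]) / diff(rng)
}

#' Min-max normalize a feature matrix per feature
#'
#' Columns are features, rows are samples; each column is mapped to [0, 1]
#' over the population (constant columns map to 0.5).
#'
#' @param m numeric matrix (samples x features).
#' @return normalized matrix of the same shape.
#' @export
normalizeFeatureMatrix <- function(m) {
  apply(m, 2L, function(v) {
    rng <- range(v)
    if (diff(rng) <= 0) rep(0.5, length(v))
    else (v - rng[1]) / diff(rng)
  })
}

#' Root-mean-square Euclidean distance between feature vectors
#'
#' \eqn{ED = \sqrt{\frac{1}{M}\sum_i (p_i - q_i)^2}} with M the feature
#' count.
#'
#' @param p,q numeric vectors of equal length.
#' @return non-negative distance.
#' @export
euclideanDistance <- function(p, q) {
  if (length(p) != length(q))
    stop("euclideanDistance: feature lengths differ")
  sqrt(mean((p - q)^2))
}

## ---- vein code serialization -------------------------------------------

CODE_MAGIC <- as.raw(c(0x56, 0x43))   # "VC"
CODE_VERSION <- 1L

#' Serialize a vein code to packed bytes
#'
#' Layout: 8-byte header (2-byte magic "VC", 2-byte version, 2-byte code
#' width, 2-byte code height, little-endian) followed by the bits packed
#' 8 per byte, most significant bit first (864 bytes for a 6,912-bit code).
#'
#' @param code a \linkS4class{VeinCode}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeVeinCode <- function(code, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(CODE_MAGIC, con)
  writeBin(as.integer(c(CODE_VERSION, code@width, code@height)), con,
           size = 2L, endian = "little")
  nb <- length(code@bits) %/% 8L
  m <- matrix(code@bits, nrow = 8L)
  bytes <- as.raw(colSums(m * 2L^(7:0)))
  writeBin(bytes, con)
  invisible(path)
}

#' Read a serialized vein code
#'
#' @param path file written by \code{\link{writeVeinCode}}.
#' @return a \linkS4class{VeinCode}.
#' @export
readVeinCode <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 2L)
  if (!identical(magic, CODE_MAGIC))
    stop("readVeinCode: not a vein-code file: ", path)
  hdr <- readBin(con, "integer", 3L, size = 2L, endian = "little")
  w <- hdr[2]; h <- hdr[3]
  nbits <- 8L * w * h
  bytes <- readBin(con, "raw", nbits %/% 8L)
  if (length(bytes) < nbits %/% 8L)
    stop("readVeinCode: truncated vein-code file: ", path)
  bits <- as.integer(rawToBits(bytes))
  # rawToBits is little-endian per byte; restore MSB-first order
  bits <- as.integer(matrix(bits, nrow = 8L)[8:1, ])
  new("VeinCode", bits = bits, width = as.integer(w), height = as.integer(h),
      bitsPerPixel = 8L)
}
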