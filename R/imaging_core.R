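## Shared image plumbing: grayscale I/O, min-max rescaling, reflect-padded
## convolution. Images are numeric matrices indexed [row, column] with the
## origin at the top-left; gray values live on the 8-bit scale [0, 255].

#' Validate a grayscale image matrix
#'
#' Checks the invariants every 8-bit image in the package must satisfy:
#' a non-empty numeric matrix with finite values in [0, 255].
#'
#' @param pixels numeric matrix, rows = y (top to bottom), columns = x.
#' @return the validated matrix, invisibly unchanged.
#' @export
grayImage <- function(pixels) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("a gray image must be a numeric matrix")
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop("a gray image must have at least one row and one column")
  if (any(!is.finite(pixels)))
    stop("gray image contains non-finite values")
  if (any(pixels < 0) || any(pixels > 255))
    stop("gray image values must lie in [0, 255]")
  pixels
}

#' Read a grayscale image
#'
#' Reads PGM (P2 ascii or P5 binary), PNG, or TIFF. RGB inputs are converted
#' to luminance with the Rec. 601 weights (0.299, 0.587, 0.114).
#'
#' @param path file path; format inferred from the extension
#'   (.pgm, .png, .tif/.tiff).
#' @return numeric matrix in [0, 255] (see \code{\link{grayImage}}).
#' @export
readGray <- function(path) {
  if (!file.exists(path)) stop("cannot read image: no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  m <- switch(ext,
    pgm = readPGM(path),
    png = {
      a <- png::readPNG(path)
      collapseLuma(a) * 255
    },
    tif = ,
    tiff = {
      a <- tiff::readTIFF(path)
      collapseLuma(a) * 255
    },
    stop("unsupported image format '", ext, "' for ", path))
  grayImage(m)
}

collapseLuma <- function(a) {
  if (length(dim(a)) == 2L) return(a)
  if (length(dim(a)) == 3L) {
    if (dim(a)[3] >= 3L)
      return(0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3])
    return(a[, , 1])
  }
  stop("unsupported raster layout")
}

#' Write a grayscale image
#'
#' @param img numeric matrix in [0, 255]; values are rounded to integers.
#' @param path output path; format from the extension. PGM is written as
#'   binary P5 unless \code{ascii = TRUE} (P2).
#' @param ascii logical, write ascii PGM instead of binary.
#' @return \code{path}, invisibly.
#' @export
writeGray <- function(img, path, ascii = FALSE) {
  img <- grayImage(img)
  v <- round(img)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    pgm = writePGM(v, path, ascii = ascii),
    png = png::writePNG(v / 255, path),
    tif = ,
    tiff = tiff::writeTIFF(v / 255, path, bits.per.sample = 8L),
    stop("unsupported image format '", ext, "' for ", path))
  invisible(path)
}

# PGM parsing is done by hand: no installed R package reads the format.
readPGM <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readPlainToken(con)
  if (!magic %in% c("P2", "P5"))
    stop("cannot read image: not a P2/P5 PGM file: ", path)
  w <- suppressWarnings(as.integer(readPlainToken(con)))
  h <- suppressWarnings(as.integer(readPlainToken(con)))
  maxval <- suppressWarnings(as.integer(readPlainToken(con)))
  if (anyNA(c(w, h, maxval)) || w < 1L || h < 1L)
    stop("cannot read image: corrupt PGM header in ", path)
  if (maxval > 255L)
    stop("cannot read image: 16-bit PGM not supported: ", path)
  n <- w * h
  vals <- if (magic == "P5") {
    raw <- readBin(con, "integer", n = n, size = 1L, signed = FALSE)
    if (length(raw) < n)
      stop("cannot read image: truncated PGM data in ", path)
    raw
  } else {
    txt <- readLines(con, warn = FALSE)
    txt <- sub("#.*$", "", txt)
    v <- suppressWarnings(as.integer(scan(text = txt, quiet = TRUE)))
    if (length(v) < n || anyNA(v[seq_len(n)]))
      stop("cannot read image: truncated PGM data in ", path)
    v[seq_len(n)]
  }
  matrix(as.numeric(vals), nrow = h, ncol = w, byrow = TRUE)
}

readPlainToken <- function(con) {
  # single whitespace-delimited token, skipping '#' comments
  tok <- ""
  repeat {
    ch <- readChar(con, 1L, useBytes = TRUE)
    if (length(ch) == 0L || ch == "") {
      if (nzchar(tok)) return(tok)
      stop("cannot read image: unexpected end of PGM header")
    }
    if (ch == "#") {
      repeat {
        ch <- readChar(con, 1L, useBytes = TRUE)
        if (length(ch) == 0L || ch == "" || ch == "\n") break
      }
      next
    }
    if (grepl("[[:space:]]", ch)) {
      if (nzchar(tok)) return(tok)
      next
    }
    tok <- paste0(tok, ch)
  }
}

writePGM <- function(v, path, ascii = FALSE) {
  h <- nrow(v); w <- ncol(v)
  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P2", paste(w, h), "255"), con)
    write(t(v), file = con, ncolumns = min(w, 17L))
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(sprintf("P5\n%d %d\n255\n", w, h), con, eos = NULL)
    writeBin(as.integer(t(v)), con, size = 1L)
  }
}

#' Affine min-max rescaling
#'
#' Maps the minimum of \code{img} to \code{lo} and the maximum to \code{hi},
#' affinely in between. A constant image maps to the midpoint
#' \code{(lo + hi) / 2}, which keeps the output in range without dividing
#' by zero.
#'
#' @param img numeric matrix with finite values.
#' @param lo,hi target range (defaults 0 and 1).
#' @return rescaled matrix of the same shape.
#' @export
rescaleMinMax <- function(img, lo = 0, hi = 1) {
  if (any(!is.finite(img))) stop("rescaleMinMax: non-finite values in input")
  mn <- min(img); mx <- max(img)
  if (mx - mn <= 0) {
    out <- img
    out[] <- (lo + hi) / 2
    return(out)
  }
  out <- lo + (img - mn) * (hi - lo) / (mx - mn)
  # guard floating-point overshoot at the endpoints
  pmin(pmax(out, min(lo, hi)), max(lo, hi))
}

## ---- padding and convolution -------------------------------------------

padReflect <- function(m, py, px) {
  # mirror padding without repeating the edge pixel beyond need:
  # indices reflect as ..., 3, 2, 1 | 1, 2, 3, ... (half-sample style,
  # edge value appears once per side per bounce)
  reflectIdx <- function(n, p) {
    idx <- seq.int(1L - p, n + p)
    per <- c(seq_len(n), rev(seq_len(n)))     # period 2n
    per[(idx - 1L) %% (2L * n) + 1L]
  }
  m[reflectIdx(nrow(m), py), reflectIdx(ncol(m), px), drop = FALSE]
}

#' 2-D convolution with reflect padding
#'
#' True convolution (verified by impulse response: \code{EBImage::filter2}
#' subtracts the kernel offset), computed on a mirror-padded copy so the
#' output has the input's shape with no wrap-around artifacts.
#'
#' @param img numeric matrix.
#' @param kernel numeric matrix with odd dimensions.
#' @return numeric matrix, same shape as \code{img}.
#' @export
convolve2d <- function(img, kernel) {
  kh <- nrow(kernel); kw <- ncol(kernel)
  if (kh %% 2L == 0L || kw %% 2L == 0L)
    stop("convolve2d: kernel dimensions must be odd")
  py <- (kh - 1L) %/% 2L
  px <- (kw - 1L) %/% 2L
  padded <- padReflect(img, py, px)
  out <- EBImage::filter2(padded, kernel, boundary = "circular")
  out[seq.int(py + 1L, py + nrow(img)), seq.int(px + 1L, px + ncol(img)),
      drop = FALSE]
}

#' Truncated unit-sum Gaussian kernel
#'
#' Isotropic Gaussian truncated at \code{radius} (default 3 sigma) and
#' renormalized so the entries sum to exactly 1.
#'
#' @param sigma standard deviation in pixels.
#' @param radius truncation radius in pixels; default \code{ceiling(3 * sigma)}.
#' @return square matrix of side \code{2 * radius + 1}.
#' @export
gaussianKernel <- function(sigma, radius = ceiling(3 * sigma)) {
  stopifnot(sigma > 0)
  d <- seq.int(-radius, radius)
  g1 <- exp(-d^2 / (2 * sigma^2))
  k <- outer(g1, g1)
  k / sum(k)
}
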