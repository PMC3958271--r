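## Periodized orthogonal wavelet-packet transform (Haar and Daubechies db2),
## written in-package: the full packet tree over three levels is what yields
## the 4^3 = 64 terminal sub-bands used as feature regions. Odd-length
## signals are extended by one repeated sample before the periodized step,
## so the forward/inverse pair reconstructs the input exactly.

waveletFilters <- function(basis = c("haar", "daubechies")) {
  basis <- match.arg(basis)
  h <- switch(basis,
    haar = c(1, 1) / sqrt(2),
    daubechies = c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) /
      (4 * sqrt(2)))
  L <- length(h)
  g <- (-1)^(seq_len(L) - 1L) * rev(h)   # quadrature mirror filter
  list(h = h, g = g)
}

# one periodized analysis step on a vector; returns list(a, d)
dwtStep <- function(x, flt) {
  n <- length(x)
  odd <- n %% 2L == 1L
  if (odd) x <- c(x, x[n])
  n <- length(x)
  half <- n %/% 2L
  a <- numeric(half); d <- numeric(half)
  ks <- 2L * seq_len(half) - 1L           # 1-based position of x[2k] term
  for (j in seq_along(flt$h)) {
    idx <- (ks + j - 2L) %% n + 1L
    a <- a + flt$h[j] * x[idx]
    d <- d + flt$g[j] * x[idx]
  }
  list(a = a, d = d, odd = odd)
}

# inverse of dwtStep; origLen recovers an odd-length input
idwtStep <- function(a, d, flt, origLen = 2L * length(a)) {
  n <- 2L * length(a)
  x <- numeric(n)
  ks <- 2L * seq_along(a) - 1L
  for (j in seq_along(flt$h)) {
    idx <- (ks + j - 2L) %% n + 1L
    contrib <- flt$h[j] * a + flt$g[j] * d
    x[idx] <- x[idx] + contrib
  }
  x[seq_len(origLen)]
}

# one 2-D packet level: returns the four children in the fixed order
# LL, LH, HL, HH (first letter = column/vertical filter, second = row).
packetStep <- function(m, flt) {
  h <- nrow(m); w <- ncol(m)
  # filter along rows (horizontal direction)
  wl <- ceiling(w / 2)
  Lr <- matrix(0, h, wl); Hr <- matrix(0, h, wl)
  for (i in seq_len(h)) {
    s <- dwtStep(m[i, ], flt)
    Lr[i, ] <- s$a; Hr[i, ] <- s$d
  }
  # then along columns (vertical direction)
  hl <- ceiling(h / 2)
  split2 <- function(B) {
    A <- matrix(0, hl, ncol(B)); D <- matrix(0, hl, ncol(B))
    for (j in seq_len(ncol(B))) {
      s <- dwtStep(B[, j], flt)
      A[, j] <- s$a; D[, j] <- s$d
    }
    list(A = A, D = D)
  }
  sL <- split2(Lr); sH <- split2(Hr)
  list(LL = sL$A, LH = sH$A, HL = sL$D, HH = sH$D)
}

inversePacketStep <- function(bands, flt, origDim) {
  h <- origDim[1]; w <- origDim[2]
  hl <- nrow(bands$LL)
  # undo the column transform
  joinCols <- function(A, D, len) {
    B <- matrix(0, len, ncol(A))
    for (j in seq_len(ncol(A)))
      B[, j] <- idwtStep(A[, j], D[, j], flt, origLen = len)
    B
  }
  Lr <- joinCols(bands$LL, bands$HL, h)
  Hr <- joinCols(bands$LH, bands$HH, h)
  m <- matrix(0, h, w)
  for (i in seq_len(h))
    m[i, ] <- idwtStep(Lr[i, ], Hr[i, ], flt, origLen = w)
  m
}

#' Full wavelet-packet decomposition
#'
#' Recursively splits every sub-band (not only the approximation) for
#' \code{levels} levels with periodized boundary handling, yielding
#' \code{4^levels} terminal sub-bands in a fixed depth-first order with
#' child order LL, LH, HL, HH.
#'
#' @param img numeric matrix.
#' @param basis \code{"haar"} or \code{"daubechies"} (db2).
#' @param levels decomposition depth (default 3, 64 terminal bands).
#' @return list of terminal sub-band matrices, with attribute
#'   \code{"dims"} recording the per-node input sizes needed for exact
#'   inversion.
#' @export
waveletPacket <- function(img, basis = c("haar", "daubechies"), levels = 3L) {
  basis <- match.arg(basis)
  flt <- waveletFilters(basis)
  dims <- list()
  recurse <- function(m, lev, key) {
    dims[[key]] <<- dim(m)
    if (lev == 0L) return(list(m))
    b <- packetStep(m, flt)
    c(recurse(b$LL, lev - 1L, paste0(key, "A")),
      recurse(b$LH, lev - 1L, paste0(key, "B")),
      recurse(b$HL, lev - 1L, paste0(key, "C")),
      recurse(b$HH, lev - 1L, paste0(key, "D")))
  }
  out <- recurse(img, as.integer(levels), "r")
  attr(out, "dims") <- dims
  attr(out, "basis") <- basis
  attr(out, "levels") <- as.integer(levels)
  out
}

#' Inverse wavelet-packet transform
#'
#' Exact inverse of \code{\link{waveletPacket}}.
#'
#' @param bands result of \code{\link{waveletPacket}}.
#' @return the reconstructed matrix.
#' @export
inverseWaveletPacket <- function(bands) {
  flt <- waveletFilters(attr(bands, "basis"))
  dims <- attr(bands, "dims")
  levels <- attr(bands, "levels")
  idx <- 0L
  rebuild <- function(lev, key) {
    if (lev == 0L) {
      idx <<- idx + 1L
      return(bands[[idx]])
    }
    ll <- rebuild(lev - 1L, paste0(key, "A"))
    lh <- rebuild(lev - 1L, paste0(key, "B"))
    hl <- rebuild(lev - 1L, paste0(key, "C"))
    hh <- rebuild(lev - 1L, paste0(key, "D"))
    inversePacketStep(list(LL = ll, LH = lh, HL = hl, HH = hh), flt,
                      dims[[key]])
  }
  rebuild(levels, "r")
}
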