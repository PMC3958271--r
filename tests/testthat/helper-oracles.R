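# Brute-force oracles and small fixtures shared across the suite. The
# oracles are written as direct definitions (explicit loops, fine grids)
# so they stay independent of the vectorized implementation paths they
# check.

# half-sample reflect index: ..., 2, 1 | 1, 2, ..., n | n, n-1, ...
oracleReflect <- function(i, n) {
  while (i < 1L || i > n) {
    if (i < 1L) i <- 1L - i
    if (i > n) i <- 2L * n + 1L - i
  }
  i
}

# direct O(n^2 k^2) true convolution with reflect padding
oracleConv <- function(img, kernel) {
  h <- nrow(img); w <- ncol(img)
  kh <- nrow(kernel); kw <- ncol(kernel)
  ry <- (kh - 1L) %/% 2L; rx <- (kw - 1L) %/% 2L
  out <- matrix(0, h, w)
  for (y in seq_len(h)) for (x in seq_len(w)) {
    acc <- 0
    for (i in seq_len(kh)) for (j in seq_len(kw)) {
      # convolution: kernel offset is subtracted
      yy <- oracleReflect(y - (i - ry - 1L), h)
      xx <- oracleReflect(x - (j - rx - 1L), w)
      acc <- acc + kernel[i, j] * img[yy, xx]
    }
    out[y, x] <- acc
  }
  out
}

# per-pixel LBP by direct neighborhood comparison
oracleLBP <- function(img) {
  h <- nrow(img); w <- ncol(img)
  offs <- list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, 1),
               c(1, 1), c(1, 0), c(1, -1), c(0, -1))
  bits <- integer(0)
  for (y in 2:(h - 1)) for (x in 2:(w - 1)) {
    for (o in offs)
      bits <- c(bits, as.integer(img[y + o[1], x + o[2]] >= img[y, x]))
  }
  bits
}

# exhaustive EER sweep over all distinct scores; smallest threshold wins
# among (near-)ties of |FAR - FRR|
oracleEER <- function(gen, imp) {
  thr <- sort(unique(c(gen, imp)))
  far <- vapply(thr, function(t) mean(imp <= t), numeric(1))
  frr <- vapply(thr, function(t) mean(gen > t), numeric(1))
  d <- abs(far - frr)
  i <- which(d <= min(d) + 1e-12)[1]
  100 * (far[i] + frr[i]) / 2
}

# fine-grid centroid of the union of the three clipped output triangles
oracleCOG <- function(hL, hM, hH, step = 1e-4) {
  x <- seq(0, 1, by = step)
  muL <- pmax(0, 1 - 2 * x); muM <- 1 - abs(2 * x - 1)
  muH <- pmax(0, 2 * x - 1)
  mu <- pmax(pmin(hL, muL), pmin(hM, muM), pmin(hH, muH))
  sum(x * mu) / sum(mu)
}

# direct sliding-window local mean/STD with oracle reflect padding
oracleLocalStats <- function(img, win) {
  h <- nrow(img); w <- ncol(img)
  r <- (win - 1L) %/% 2L
  mu <- matrix(0, h, w); sd <- matrix(0, h, w)
  for (y in seq_len(h)) for (x in seq_len(w)) {
    vals <- numeric(0)
    for (i in -r:r) for (j in -r:r)
      vals <- c(vals, img[oracleReflect(y + i, h), oracleReflect(x + j, w)])
    mu[y, x] <- mean(vals)
    sd[y, x] <- sqrt(mean((vals - mean(vals))^2))
  }
  list(mean = mu, std = sd)
}

# the worked-example membership outputs and the printed inference table
workedMemberships <- function() {
  list(f1 = c(L = 0.39, H = 0.61), f2 = c(L = 0.55, H = 0.45),
       f3 = c(L = 0.67, H = 0.33), f4 = c(L = 0.27, H = 0.73))
}

# all 16 printed rows: antecedent labels, Min IV, Max IV, consequent label
printedInferenceTable <- function() {
  data.frame(
    lab1 = rep(c("L", "H"), each = 8),
    lab2 = rep(rep(c("L", "H"), each = 4), 2),
    lab3 = rep(rep(c("L", "H"), each = 2), 4),
    lab4 = rep(c("L", "H"), 8),
    minIV = c(0.27, 0.39, 0.27, 0.33, 0.27, 0.39, 0.27, 0.33,
              0.27, 0.55, 0.27, 0.33, 0.27, 0.45, 0.27, 0.33),
    maxIV = c(0.67, 0.73, 0.55, 0.73, 0.67, 0.73, 0.45, 0.73,
              0.67, 0.73, 0.61, 0.73, 0.67, 0.73, 0.61, 0.73),
    label = c("M", "L", "M", "L", "H", "M", "H", "H",
              "M", "L", "M", "L", "H", "L", "H", "M"),
    stringsAsFactors = FALSE)
}

# small fixture: illuminated band with one dark curvilinear vessel
vesselFixture <- function(n = 64, drop = 50, ramp = 40, seed = 5) {
  set.seed(seed)
  base <- 160 + outer(rep(0, n), seq(-ramp / 2, ramp / 2, length.out = n),
                      "+")
  center <- n / 2 + 4 * sin(seq(0, 2 * pi, length.out = n))
  for (x in seq_len(n)) {
    rows <- which(abs(seq_len(n) - center[x]) <= 2)
    base[rows, x] <- base[rows, x] - drop
  }
  pmin(pmax(base, 0), 255)
}
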