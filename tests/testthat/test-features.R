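flatRoi <- function(w, h) {
  new("FingerROI", upperY = rep(1L, w), lowerY = rep(as.integer(h), w),
      x1 = 0L, x2 = 0L, degenerate = FALSE)
}

test_that("size normalization is the identity on already-normal input", {
  set.seed(50)
  img <- matrix(runif(60 * 150, 0, 255), 60, 150)
  out <- normalizeSize(img, flatRoi(150, 60))
  expect_equal(out, img, tolerance = 1e-12)
})

test_that("uniform 2:1 scaling matches a per-column resampling oracle", {
  set.seed(51)
  img <- matrix(runif(120 * 300, 0, 255), 120, 300)
  out <- normalizeSize(img, flatRoi(300, 120))
  expect_identical(dim(out), c(60L, 150L))
  # oracle: first output column maps to the first input column; its rows
  # are a plain linear resample of that column
  atY <- seq(1, 120, length.out = 60)
  expect_equal(out[, 1], approx(1:120, img[, 1], xout = atY)$y,
               tolerance = 1e-12)
})

test_that("wedge-shaped boundaries are straightened", {
  # boundaries diverge linearly; a line midway between them must map to
  # the middle output row everywhere
  w <- 200L; h <- 120L
  up <- as.integer(round(seq(10, 40, length.out = w)))
  lo <- as.integer(round(seq(70, 110, length.out = w)))
  img <- matrix(180, h, w)
  for (x in seq_len(w)) img[round((up[x] + lo[x]) / 2), x] <- 0
  roi <- new("FingerROI", upperY = up, lowerY = lo, x1 = 0L, x2 = 0L,
             degenerate = FALSE)
  out <- normalizeSize(img, roi)
  darkRow <- apply(out, 2, which.min)
  expect_true(all(abs(darkRow - 30) <= 2))
})

test_that("3x3 block averaging tiles exactly", {
  expect_equal(downsample3x3(matrix(9, 60, 150)), matrix(9, 20, 50))
  img <- matrix(0, 60, 150)
  img[1:3, 1:3] <- matrix(0:8, 3, 3)
  expect_equal(downsample3x3(img)[1, 1], 4)
  checker <- 255 * (outer(1:60, 1:150, "+") %% 2)
  down <- downsample3x3(checker)
  expect_true(all(abs(down - mean(checker)) < 30))
  expect_error(downsample3x3(matrix(0, 50, 20)), "150")
})

test_that("LBP codes are 6,912 bits with the >= tie convention", {
  code <- lbpCode(matrix(42, 20, 50))
  expect_identical(length(veinBits(code)), 6912L)
  expect_true(all(veinBits(code) == 1L))   # ties give 1
  # a single bright pixel: its own code is all zeros (neighbors below it)
  img <- matrix(100, 20, 50); img[10, 25] <- 200
  bits <- veinBits(lbpCode(img))
  px <- matrix(bits, nrow = 8L)   # one column per interior pixel, row-major
  idx <- (10 - 2) * 48 + (25 - 1)  # row-major interior index of (10, 25)
  expect_true(all(px[, idx] == 0L))
  expect_error(lbpCode(matrix(0, 50, 20)), "50")
})

test_that("LBP matches the brute-force neighborhood oracle", {
  set.seed(52)
  for (rep in 1:3) {
    img <- matrix(sample(0:255, 1000, replace = TRUE), 20, 50)
    expect_identical(veinBits(lbpCode(img)), oracleLBP(img))
  }
})

test_that("Hamming distance endpoints and metric axioms hold", {
  set.seed(53)
  mk <- function(bits) new("VeinCode", bits = bits, width = 48L,
                           height = 18L, bitsPerPixel = 8L)
  a <- mk(sample(0:1, 6912, replace = TRUE))
  expect_equal(hammingDistance(a, a), 0)
  expect_equal(hammingDistance(a, mk(1L - veinBits(a))), 1)
  b <- mk(c(1L - veinBits(a)[1:3456], veinBits(a)[3457:6912]))
  expect_equal(hammingDistance(a, b), 0.5)
  for (rep in 1:20) {
    x <- mk(sample(0:1, 6912, replace = TRUE))
    y <- mk(sample(0:1, 6912, replace = TRUE))
    z <- mk(sample(0:1, 6912, replace = TRUE))
    expect_equal(hammingDistance(x, y), hammingDistance(y, x))
    expect_lte(hammingDistance(x, z),
               hammingDistance(x, y) + hammingDistance(y, z) + 1e-12)
  }
})

test_that("wavelet packets invert exactly and count 64 sub-bands", {
  set.seed(54)
  img <- matrix(runif(20 * 50, 0, 255), 20, 50)
  for (basis in c("haar", "daubechies")) {
    wp <- waveletPacket(img, basis)
    expect_identical(length(wp), 64L)
    expect_equal(inverseWaveletPacket(wp), img, tolerance = 1e-9)
  }
  # odd-length signals also round-trip
  odd <- matrix(runif(15 * 27), 15, 27)
  expect_equal(inverseWaveletPacket(waveletPacket(odd, "daubechies")), odd,
               tolerance = 1e-9)
})

test_that("one Haar level of a 2x2 block gives (a+b+c+d)/2", {
  m <- matrix(c(3, 7, 1, 5), 2, 2)    # a=3, c=7 / b=1, d=5 column layout
  b <- veinfuse:::packetStep(m, veinfuse:::waveletFilters("haar"))
  expect_equal(as.numeric(b$LL), sum(m) / 2, tolerance = 1e-12)
})

test_that("wavelet features: 128 values, constant input concentrates", {
  f <- waveletFeatures(matrix(runif(1000, 0, 255), 20, 50), "haar")
  expect_identical(length(f), 128L)
  expect_true(all(f >= 0 & f <= 1))
  raw <- waveletFeatures(matrix(10, 20, 50), "haar", normalize = FALSE)
  means <- raw[seq(1, 128, by = 2)]
  stds <- raw[seq(2, 128, by = 2)]
  expect_true(all(abs(stds) < 1e-9))
  expect_gt(means[1], 0)                    # approximation band
  expect_true(all(abs(means[-1]) < 1e-9))   # every detail band
})

test_that("Euclidean distance is the RMS difference and a metric", {
  expect_equal(euclideanDistance(1:5, 1:5), 0)
  expect_equal(euclideanDistance(rep(2, 8), rep(5, 8)), 3)
  expect_equal(euclideanDistance(c(1, 0), c(0, 1)), 1)
  expect_error(euclideanDistance(1:3, 1:4), "lengths")
  set.seed(55)
  for (rep in 1:20) {
    p <- runif(16); q <- runif(16); r <- runif(16)
    expect_equal(euclideanDistance(p, q), euclideanDistance(q, p))
    expect_lte(euclideanDistance(p, r),
               euclideanDistance(p, q) + euclideanDistance(q, r) + 1e-12)
  }
})

test_that("vein codes serialize to packed bytes and back", {
  set.seed(56)
  code <- lbpCode(matrix(sample(0:255, 1000, TRUE), 20, 50))
  p <- withr::local_tempfile(fileext = ".vc")
  writeVeinCode(code, p)
  expect_identical(file.size(p), 8 + 6912 / 8)  # header + 864 bytes
  back <- readVeinCode(p)
  expect_identical(veinBits(back), veinBits(code))
  expect_identical(back@width, 48L)
  q <- withr::local_tempfile(fileext = ".vc")
  writeBin(as.raw(1:4), q)
  expect_error(readVeinCode(q), "not a vein-code")
})
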