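stepImage <- function(h, w, edge1, edge2, dark = 20, bright = 200) {
  m <- matrix(dark, h, w)
  m[edge1:edge2, ] <- bright
  m
}

test_that("boundary masks are zero-sum mirrored edge templates", {
  up <- boundaryMask("upper")
  lo <- boundaryMask("lower")
  expect_identical(dim(up), c(4L, 20L))
  expect_equal(sum(up), 0)
  expect_equal(sum(lo), 0)
  expect_equal(lo, up[4:1, ])
})

test_that("detectBoundaries finds step edges at every column", {
  img <- stepImage(240, 64, 101, 140)
  roi <- detectBoundaries(img)
  expect_true(all(abs(upperBoundary(roi) - 101) <= 2))
  expect_true(all(abs(lowerBoundary(roi) - 140) <= 2))
  expect_false(roi@degenerate)
})

test_that("boundaries swap roles symmetrically under vertical mirroring", {
  img <- stepImage(200, 40, 61, 130)
  flipped <- img[200:1, ]
  a <- detectBoundaries(img)
  b <- detectBoundaries(flipped)
  expect_equal(upperBoundary(b), 200L + 1L - lowerBoundary(a))
  expect_equal(lowerBoundary(b), 200L + 1L - upperBoundary(a))
})

test_that("detection equals an exhaustive per-column argmax oracle", {
  set.seed(10)
  img <- matrix(runif(64 * 64, 0, 255), 64, 64)
  roi <- detectBoundaries(img)
  h <- 64L; half <- 2L
  # oracle: direct template response scan, smallest row on ties
  for (x in c(10, 32, 54)) {
    best <- -Inf; bestY <- NA
    for (y in seq.int(half + 1L, h %/% 2L)) {
      r <- sum(img[y:(y + 1L), (x - 9):(x + 10)]) -
        sum(img[(y - 2L):(y - 1L), (x - 9):(x + 10)])
      if (r > best) { best <- r; bestY <- y }
    }
    expect_identical(upperBoundary(roi)[x], as.integer(bestY))
    best <- -Inf; bestY <- NA
    for (y in seq.int(h %/% 2L + 1L, h - half)) {
      r <- sum(img[(y - 1L):y, (x - 9):(x + 10)]) -
        sum(img[(y + 1L):(y + 2L), (x - 9):(x + 10)])
      if (r > best) { best <- r; bestY <- y }
    }
    expect_identical(lowerBoundary(roi)[x], as.integer(bestY))
  }
})

test_that("uniform images are flagged degenerate with smallest-row ties", {
  img <- matrix(100, 60, 40)
  roi <- detectBoundaries(img)
  expect_true(roi@degenerate)
  expect_identical(unique(upperBoundary(roi)), 3L)  # first feasible row
  expect_identical(unique(lowerBoundary(roi)), 31L) # first row of lower band
})

test_that("detectBoundaries rejects images narrower than the mask", {
  expect_error(detectBoundaries(matrix(1, 60, 19)), "narrower")
  expect_error(detectBoundaries(matrix(1, 7, 40)), "twice")
})

test_that("crop profiles retain the documented column spans", {
  imgI <- stepImage(480, 640, 101, 380)
  roiI <- detectBoundaries(imgI)
  expect_equal(ncol(cropRoi(imgI, roiI, "database_I")$image),
               640 - 220 - 169)   # 251
  imgII <- stepImage(240, 320, 51, 190)
  roiII <- detectBoundaries(imgII)
  cropII <- cropRoi(imgII, roiII, "database_II")
  expect_equal(ncol(cropII$image), 320 - 20 - 51)   # 249
  # database_II also trims rows vertically relative to the plain crop
  plain <- cropRoi(imgII, roiII, "database_II", verticalInset = 0L)
  expect_equal(nrow(cropII$image), nrow(plain$image) - 8L)
})

test_that("crop with x1 = x2 = 0 and edge boundaries is the identity", {
  img <- stepImage(60, 40, 1, 60, dark = 50, bright = 50)
  roi <- new("FingerROI", upperY = rep(1L, 40), lowerY = rep(60L, 40),
             x1 = 0L, x2 = 0L, degenerate = FALSE)
  out <- cropRoi(img, roi)
  expect_identical(out$image, img)
  expect_identical(upperBoundary(out$roi), rep(1L, 40))
  expect_identical(lowerBoundary(out$roi), rep(60L, 40))
})

test_that("degenerate crops raise errors", {
  img <- stepImage(60, 40, 21, 40)
  roi <- detectBoundaries(img)
  expect_error(cropRoi(img, roi, verticalInset = 40L), "degenerate")
})

test_that("crop dimensions follow (width, x1, x2, boundary extrema)", {
  set.seed(11)
  for (i in 1:5) {
    h <- sample(60:120, 1); w <- sample(40:80, 1)
    e1 <- sample(10:(h %/% 2 - 3), 1); e2 <- sample((h %/% 2 + 5):(h - 10), 1)
    img <- stepImage(h, w, e1, e2)
    roi <- detectBoundaries(img)
    out <- cropRoi(img, roi)
    cols <- seq_len(w)
    expect_identical(dim(out$image),
                     c(max(lowerBoundary(roi)) - min(upperBoundary(roi)) + 1L,
                       w))
  }
})
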