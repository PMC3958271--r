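test_that("membership ramps are complementary and clamp out-of-range", {
  m <- membershipPair(0.61)
  expect_equal(m$low, 0.39)
  expect_equal(m$high, 0.61)
  expect_equal(membershipPair(0), list(low = 1, high = 0))
  expect_equal(membershipPair(0.5), list(low = 0.5, high = 0.5))
  expect_warning(out <- membershipPair(1.2), "clamped")
  expect_equal(out$high, 1)
  # vectorized shapes pass through
  m2 <- membershipPair(matrix(c(0.2, 0.8), 1))
  expect_equal(m2$low + m2$high, matrix(1, 1, 2))
})

test_that("the rule base is total over the 16 antecedent quadruples", {
  rules <- defaultRuleTable()
  expect_identical(nrow(rules), 16L)
  expect_identical(anyDuplicated(rules[, 1:4]), 0L)
  expect_true(all(rules$out %in% c("L", "M", "H")))
})

test_that("the worked example reproduces the printed inference table", {
  grid <- inferenceGrid(0.61, 0.45, 0.33, 0.73)
  ref <- printedInferenceTable()
  expect_equal(grid$minIV, ref$minIV, tolerance = 1e-12)
  expect_equal(grid$maxIV, ref$maxIV, tolerance = 1e-12)
  expect_identical(grid$label, ref$label)
  expect_identical(grid$lab1, ref$lab1)
  expect_identical(grid$lab4, ref$lab4)
})

test_that("inference equals an exhaustive oracle on random memberships", {
  set.seed(40)
  rules <- defaultRuleTable()
  for (rep in 1:250) {
    x <- runif(4)
    ms <- lapply(x, membershipPair)
    for (mode in c("min", "max")) {
      ivs <- inferIV(ms[[1]], ms[[2]], ms[[3]], ms[[4]], rules, mode)
      # oracle: explicit degree lookup per rule row
      for (i in seq_len(16)) {
        degs <- vapply(1:4, function(j) {
          lab <- rules[i, j]
          if (lab == "L") 1 - x[j] else x[j]
        }, numeric(1))
        want <- if (mode == "min") min(degs) else max(degs)
        expect_equal(ivs[[i]]$value, want, tolerance = 1e-12)
        expect_identical(ivs[[i]]$label, rules$out[i])
      }
    }
  }
})

mkIVs <- function(vL, vM, vH) {
  # minimal IV list with one rule per consequent label
  list(list(label = "L", value = vL),
       list(label = "M", value = vM),
       list(label = "H", value = vH))
}

test_that("single-peak and symmetric defuzzification cases", {
  ivs <- mkIVs(0, 1, 0)
  for (m in c("fom", "lom", "mom", "meom"))
    expect_equal(as.numeric(defuzzify(ivs, m)), 0.5)
  # equal L and H levels: centroid at the midpoint by symmetry
  expect_equal(as.numeric(defuzzify(mkIVs(0.6, 0, 0.6), "cog")), 0.5,
               tolerance = 1e-9)
  # all-zero IVs fall back to the neutral weight
  expect_message(w <- defuzzify(mkIVs(0, 0, 0), "lom"), "neutral")
  expect_equal(as.numeric(w), 0.5)
})

test_that("defuzzifiers stay in [0,1] and order FOM <= MOM <= LOM", {
  set.seed(41)
  for (rep in 1:200) {
    ivs <- mkIVs(runif(1), runif(1), runif(1))
    vals <- vapply(c("fom", "mom", "lom", "meom", "cog"),
                   function(m) as.numeric(defuzzify(ivs, m)), numeric(1))
    expect_true(all(vals >= 0 & vals <= 1))
    expect_lte(vals["fom"], vals["mom"] + 1e-12)
    expect_lte(vals["mom"], vals["lom"] + 1e-12)
  }
})

test_that("the analytic centroid matches a fine-grid oracle", {
  # worked-example Min-rule IVs aggregate to (L, M, H) = (0.55, 0.39, 0.33)
  ms <- lapply(c(0.61, 0.45, 0.33, 0.73), membershipPair)
  ivs <- inferIV(ms[[1]], ms[[2]], ms[[3]], ms[[4]], mode = "min")
  agg <- vapply(c("L", "M", "H"), function(lab)
    max(vapply(ivs[vapply(ivs, `[[`, "", "label") == lab],
               function(x) x$value, numeric(1))), numeric(1))
  expect_equal(unname(agg), c(0.55, 0.39, 0.33))
  expect_equal(as.numeric(defuzzify(ivs, "cog")),
               oracleCOG(agg[1], agg[2], agg[3]), tolerance = 1e-3)
  # random levels
  set.seed(42)
  for (rep in 1:50) {
    h <- runif(3)
    expect_equal(as.numeric(defuzzify(mkIVs(h[1], h[2], h[3]), "cog")),
                 oracleCOG(h[1], h[2], h[3]), tolerance = 1e-3)
  }
})

test_that("local statistics match a sliding-window oracle", {
  set.seed(43)
  img <- matrix(runif(16 * 16, 0, 255), 16, 16)
  ref <- oracleLocalStats(img, 5L)
  st <- localStats(img, img, window = 5L)
  expect_equal(st$mu1, rescaleMinMax(ref$mean), tolerance = 1e-9)
  expect_equal(st$std1, rescaleMinMax(ref$std), tolerance = 1e-9)
  # STD is maximal exactly where the window contains the dark line
  line <- matrix(200, 16, 16); line[8, ] <- 10
  stl <- localStats(line, line, window = 5L)
  expect_true(all(apply(stl$std1[, 3:14], 2, which.max) %in% 6:10))
  expect_true(all(stl$std1[8, ] == max(stl$std1)))
  # constant image: zero STD everywhere, midpoint after normalization
  stc <- localStats(matrix(7, 10, 10), matrix(7, 10, 10), window = 3L)
  expect_true(all(stc$std1 == 0.5))
  expect_error(localStats(img, img[, 1:8], 5L), "shape")
  expect_error(localStats(img, img, 4L), "odd")
})

test_that("fusing identical inputs returns them for every setting", {
  set.seed(44)
  img <- matrix(runif(30 * 30, 0, 255), 30, 30)
  for (rule in c("min", "max"))
    for (m in c("fom", "lom", "cog")) {
      out <- fuseImages(img, img, window = 5L, rule = rule, method = m)
      expect_equal(out$image, img, tolerance = 1e-9)
    }
})

test_that("the fused image is the weighted combination of its inputs", {
  set.seed(45)
  g <- matrix(runif(24 * 24, 0, 255), 24, 24)
  r <- matrix(runif(24 * 24, 0, 255), 24, 24)
  out <- fuseImages(g, r, window = 5L)
  expect_true(all(out$weights >= 0 & out$weights <= 1))
  expect_equal(out$image, out$weights * g + (1 - out$weights) * r,
               tolerance = 1e-12)
  # monotone in w: the weight-1 endpoint is the Gabor input itself
  expect_equal(1 * g + (1 - 1) * r, g)
  expect_error(fuseImages(g, r[, 1:8], 5L), "shape")
})

test_that("fusion reduces skin noise relative to the Retinex input", {
  spec <- syntheticSpec(seed = 1)
  li <- generateImage(spec)
  roi <- detectBoundaries(li@image, x1 = 10, x2 = 10)
  cr <- cropRoi(li@image, roi, verticalInset = 15)
  crM <- cropRoi(ifelse(li@mask, 255, 0), roi, verticalInset = 15)
  skin <- crM$image <= 127
  gab <- applyGaborBank(cr$image)
  ret <- ssr(cr$image)
  fused <- fuseImages(gab, ret, rule = "min", method = "lom")$image
  expect_lt(sd(fused[skin]), sd(ret[skin]))
})
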