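## Pixel-wise fuzzy fusion of the Gabor and Retinex images.
##
## At every pixel, four crisp inputs -- the min-max normalized local mean
## and STD of each filtered image -- are fuzzified into Low/High degrees by
## complementary linear ramps, pushed through a 16-rule Mamdani rule base,
## and defuzzified into a weight w in [0, 1] for the Gabor image (the
## Retinex image gets 1 - w). A window containing a vein line has a low
## mean (veins are dark) and a high STD, which is what the rule base
## rewards.

#' The 16-rule fusion rule base
#'
#' Antecedents are the L/H labels of (mu1, std1) from the Gabor image and
#' (mu2, std2) from the Retinex image; the consequent is the L/M/H label of
#' the Gabor weight. Rows are ordered with the last input cycling fastest
#' and L before H, the order used throughout the package.
#'
#' @return data.frame with columns mu1, std1, mu2, std2, out.
#' @export
defaultRuleTable <- function() {
  g <- expand.grid(std2 = c("L", "H"), mu2 = c("L", "H"),
                   std1 = c("L", "H"), mu1 = c("L", "H"),
                   stringsAsFactors = FALSE)[, 4:1]
  g$out <- c("M", "L", "M", "L", "H", "M", "H", "H",
             "M", "L", "M", "L", "H", "L", "H", "M")
  g
}

#' Fuzzify a normalized statistic
#'
#' Complementary linear ramps on [0, 1]: degree of High is x itself, degree
#' of Low is 1 - x, so the pair always sums to one. Inputs outside [0, 1]
#' are clamped with a warning.
#'
#' @param x numeric vector/matrix of normalized statistics.
#' @return list with elements \code{low} and \code{high}, same shape as x.
#' @export
membershipPair <- function(x) {
  if (any(x < 0 | x > 1)) {
    warning("membershipPair: input outside [0, 1] clamped")
    x <- pmin(pmax(x, 0), 1)
  }
  list(low = 1 - x, high = x)
}

#' Rule-wise inference values
#'
#' For each of the 16 antecedent label quadruples, combines the four
#' membership degrees with the Min (or Max) operator. Each element of the
#' result carries the inference value (IV) and the rule's consequent label.
#'
#' @param m1,m2,m3,m4 membership pairs from \code{\link{membershipPair}}
#'   for mu1, std1, mu2, std2 (vectorized shapes allowed).
#' @param rules rule base from \code{\link{defaultRuleTable}}.
#' @param mode \code{"min"} or \code{"max"}.
#' @return list of 16 elements, each \code{list(label=, value=)}.
#' @export
inferIV <- function(m1, m2, m3, m4, rules = defaultRuleTable(),
                    mode = c("min", "max")) {
  mode <- match.arg(mode)
  if (nrow(rules) != 16L || anyDuplicated(rules[, 1:4]))
    stop("inferIV: rule table must map all 16 antecedent quadruples")
  comb <- if (mode == "min") pmin else pmax
  pick <- function(m, lab) if (lab == "L") m$low else m$high
  lapply(seq_len(16L), function(i) {
    r <- rules[i, ]
    v <- comb(pick(m1, r$mu1), pick(m2, r$std1),
              pick(m3, r$mu2), pick(m4, r$std2))
    list(label = r$out, value = v)
  })
}

## output membership triangles on [0, 1]:
##   L = (0, 0, 0.5), M = (0, 0.5, 1), H = (0.5, 1, 1)
## plateau of the set clipped at level m (the region where the label's
## membership is >= m):
##   L: [0, (1 - m)/2]   M: [m/2, 1 - m/2]   H: [(1 + m)/2, 1]

outputMembership <- function(x) {
  # keep the first pmax argument non-scalar so dim attributes survive
  list(L = pmax(1 - 2 * x, 0),
       M = 1 - abs(2 * x - 1),
       H = pmax(2 * x - 1, 0))
}

aggregateIV <- function(ivs) {
  agg <- list(L = NULL, M = NULL, H = NULL)
  for (iv in ivs) {
    lab <- iv$label
    agg[[lab]] <- if (is.null(agg[[lab]])) iv$value
                  else pmax(agg[[lab]], iv$value)
  }
  zero <- ivs[[1]]$value * 0
  lapply(agg, function(a) if (is.null(a)) zero else a)
}

#' Defuzzify inference values into a crisp weight
#'
#' IVs are aggregated per consequent label by maximum, the three output
#' triangles are clipped at those levels, and the crisp weight is read off
#' the clipped union: FOM / LOM / MOM / MeOM use the crossing points of the
#' overall maximum level with the output sets attaining it (smallest,
#' largest, midpoint of first and last, mean of the distinct crossings);
#' COG returns the exact area centroid of the union, integrated piecewise
#' over the breakpoints of the clipped piecewise-linear membership curve.
#' If every IV is zero the weight falls back to the neutral 0.5 (with a
#' message).
#'
#' @param ivs inference values from \code{\link{inferIV}} (vectorized
#'   shapes allowed; the result has the shape of the IV values).
#' @param method one of \code{"fom"}, \code{"lom"}, \code{"mom"},
#'   \code{"meom"}, \code{"cog"}.
#' @return numeric weight(s) in [0, 1].
#' @export
defuzzify <- function(ivs, method = c("fom", "lom", "mom", "meom", "cog")) {
  method <- match.arg(method)
  agg <- aggregateIV(ivs)
  shape <- agg$L
  hL <- as.numeric(agg$L); hM <- as.numeric(agg$M); hH <- as.numeric(agg$H)
  m <- pmax(hL, hM, hH)
  dead <- m <= 0
  if (any(dead)) message("defuzzify: all inference values zero at ",
                         sum(dead), " position(s); using neutral weight 0.5")

  w <- if (method == "cog") cogCentroid(hL, hM, hH)
       else maximaDefuzz(hL, hM, hH, m, method)
  w[dead] <- 0.5
  out <- shape
  out[] <- pmin(pmax(w, 0), 1)
  out
}

maximaDefuzz <- function(hL, hM, hH, m, method) {
  tol <- 1e-12
  atL <- hL >= m - tol; atM <- hM >= m - tol; atH <- hH >= m - tol
  loL <- ifelse(atL, 0, NA_real_)
  hiL <- ifelse(atL, (1 - m) / 2, NA_real_)
  loM <- ifelse(atM, m / 2, NA_real_)
  hiM <- ifelse(atM, 1 - m / 2, NA_real_)
  loH <- ifelse(atH, (1 + m) / 2, NA_real_)
  hiH <- ifelse(atH, 1, NA_real_)
  fom <- pmin(loL, loM, loH, na.rm = TRUE)
  lom <- pmax(hiL, hiM, hiH, na.rm = TRUE)
  switch(method,
    fom = fom,
    lom = lom,
    mom = (fom + lom) / 2,
    meom = {
      cand <- cbind(loL, hiL, loM, hiM, loH, hiH)
      apply(cand, 1L, function(v) mean(unique(round(v[!is.na(v)], 9L))))
    })
}

# Exact centroid of the union of the three clipped triangles. The union
# membership max_k min(h_k, mu_k(x)) is piecewise linear; between
# consecutive candidate breakpoints no two pieces cross, so evaluating at
# the breakpoints and integrating each linear segment in closed form is
# exact.
cogCentroid <- function(hL, hM, hH) {
  n <- length(hL)
  bp <- cbind(0, 0.25, 0.5, 0.75, 1,
              (1 - hL) / 2, hL / 2, 1 - hL / 2, (1 + hL) / 2,
              (1 - hM) / 2, hM / 2, 1 - hM / 2, (1 + hM) / 2,
              (1 - hH) / 2, hH / 2, 1 - hH / 2, (1 + hH) / 2)
  bp <- matrix(pmin(pmax(bp, 0), 1), nrow = n)
  ord <- matrix(t(apply(bp, 1L, sort)), nrow = n)
  mu <- function(x) {
    f <- outputMembership(x)
    # hL/hM/hH recycle down columns, matching the pixel-per-row layout
    pmax(pmin(f$L, hL), pmin(f$M, hM), pmin(f$H, hH))
  }
  y <- matrix(mu(ord), nrow = n)
  k <- ncol(ord)
  x1 <- ord[, -k, drop = FALSE]; x2 <- ord[, -1L, drop = FALSE]
  y1 <- y[, -k, drop = FALSE];  y2 <- y[, -1L, drop = FALSE]
  len <- x2 - x1
  area <- len * (y1 + y2) / 2
  # moment of a linear segment: int x * (y1 + (y2-y1)(x-x1)/len) dx
  mom <- y1 * (x2^2 - x1^2) / 2 +
    ifelse(len > 0,
           (y2 - y1) / ifelse(len > 0, len, 1) *
             ((x2^3 - x1^3) / 3 - x1 * (x2^2 - x1^2) / 2),
           0)
  A <- rowSums(area); M <- rowSums(mom)
  ifelse(A > 0, M / A, 0.5)
}

#' Local window statistics of the two filtered images
#'
#' Mean and population STD in the square window centered at every pixel
#' (reflect-padded, 1-pixel step), each of the four maps then min-max
#' normalized to [0, 1] over the whole image. The window side should be
#' about twice the widest vein line (default 21 for a 10-pixel maximum
#' width).
#'
#' @param gaborImg,retinexImg numeric matrices of the same shape.
#' @param window odd window side >= 3.
#' @return list with matrices mu1, std1, mu2, std2 and the window size.
#' @export
localStats <- function(gaborImg, retinexImg, window = 21L) {
  if (!identical(dim(gaborImg), dim(retinexImg)))
    stop("localStats: images must have the same shape")
  if (window < 3L || window %% 2L == 0L)
    stop("localStats: window must be odd and >= 3")
  box <- matrix(1 / window^2, window, window)
  stat <- function(img) {
    m1 <- convolve2d(img, box)
    m2 <- convolve2d(img^2, box)
    list(mean = m1, std = sqrt(pmax(m2 - m1^2, 0)))
  }
  sg <- stat(gaborImg); sr <- stat(retinexImg)
  list(mu1 = rescaleMinMax(sg$mean), std1 = rescaleMinMax(sg$std),
       mu2 = rescaleMinMax(sr$mean), std2 = rescaleMinMax(sr$std),
       window = as.integer(window))
}

#' Fuse the Gabor and Retinex images
#'
#' Runs the full per-pixel chain local statistics -> fuzzification ->
#' 16-rule inference -> defuzzification, and combines the images as
#' \eqn{V_O = w V_G + (1 - w) V_R}.
#'
#' @param gaborImg,retinexImg numeric matrices in [0, 255], same shape.
#' @param window local window side (odd, >= 3).
#' @param rule inference operator, \code{"min"} or \code{"max"}.
#' @param method defuzzifier (see \code{\link{defuzzify}}); the default
#'   \code{"lom"} with the Min rule is the configuration with the best
#'   verification accuracy on high-resolution imagery.
#' @param rules rule base (see \code{\link{defaultRuleTable}}).
#' @return list with \code{image} (fused matrix in [0, 255]) and
#'   \code{weights} (the per-pixel Gabor weight map in [0, 1]).
#' @export
fuseImages <- function(gaborImg, retinexImg, window = 21L,
                       rule = c("min", "max"),
                       method = c("lom", "fom", "mom", "meom", "cog"),
                       rules = defaultRuleTable()) {
  rule <- match.arg(rule)
  method <- match.arg(method)
  gaborImg <- grayImage(gaborImg); retinexImg <- grayImage(retinexImg)
  if (!identical(dim(gaborImg), dim(retinexImg)))
    stop("fuseImages: images must have the same shape")
  st <- localStats(gaborImg, retinexImg, window)
  ivs <- inferIV(membershipPair(st$mu1), membershipPair(st$std1),
                 membershipPair(st$mu2), membershipPair(st$std2),
                 rules = rules, mode = rule)
  w <- defuzzify(ivs, method)
  fused <- w * gaborImg + (1 - w) * retinexImg
  list(image = grayImage(fused), weights = w)
}

#' Reproduce the 16-pair inference grid from four normalized inputs
#'
#' Utility mirroring the worked defuzzification example: given the four
#' normalized statistics, lists all 16 antecedent combinations with their
#' membership degrees, Min-rule and Max-rule inference values and
#' consequent labels.
#'
#' @param mu1,std1,mu2,std2 normalized statistics in [0, 1]. The defaults
#'   are the worked-example inputs (memberships 0.39/0.61, 0.55/0.45,
#'   0.67/0.33, 0.27/0.73).
#' @return data.frame with 16 rows: pair, f1..f4, their labels, minIV,
#'   maxIV, label.
#' @export
inferenceGrid <- function(mu1 = 0.61, std1 = 0.45, mu2 = 0.33, std2 = 0.73) {
  ms <- list(membershipPair(mu1), membershipPair(std1),
             membershipPair(mu2), membershipPair(std2))
  rules <- defaultRuleTable()
  ivMin <- inferIV(ms[[1]], ms[[2]], ms[[3]], ms[[4]], rules, "min")
  ivMax <- inferIV(ms[[1]], ms[[2]], ms[[3]], ms[[4]], rules, "max")
  pick <- function(m, lab) if (lab == "L") m$low else m$high
  out <- rules[, 1:4]
  names(out) <- c("lab1", "lab2", "lab3", "lab4")
  for (j in 1:4)
    out[[paste0("f", j)]] <- vapply(seq_len(16L), function(i)
      pick(ms[[j]], rules[i, j]), numeric(1))
  out$minIV <- vapply(ivMin, function(x) as.numeric(x$value), numeric(1))
  out$maxIV <- vapply(ivMax, function(x) as.numeric(x$value), numeric(1))
  out$label <- rules$out
  cbind(pair = seq_len(16L), out)
}
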