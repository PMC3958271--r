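## Verification evaluation: all-pairs genuine/imposter matching, FAR/FRR
## threshold sweep, EER and ROC. Scores are distances throughout;
## acceptance means distance <= threshold.

#' Authentic and imposter pair counts for an all-pairs gallery
#'
#' With every image both enrolling and probing, a gallery of
#' \code{classes} fingers with \code{imagesPerClass} samples each yields
#' \code{choose(imagesPerClass, 2) * classes} authentic pairs and
#' \code{choose(total, 2)} minus that many imposter pairs.
#'
#' @param classes number of distinct fingers.
#' @param imagesPerClass samples per finger.
#' @return named numeric vector \code{c(authentic=, imposter=)}.
#' @export
countPairs <- function(classes, imagesPerClass) {
  if (classes < 1L) stop("countPairs: classes must be >= 1")
  if (imagesPerClass < 2L)
    warning("countPairs: fewer than 2 images per class, no authentic pairs")
  authentic <- choose(imagesPerClass, 2) * classes
  total <- classes * imagesPerClass
  c(authentic = authentic, imposter = choose(total, 2) - authentic)
}

#' Build a ScoreSet
#'
#' @param genuine,imposter numeric distance vectors.
#' @return a \linkS4class{ScoreSet}.
#' @export
scoreSet <- function(genuine, imposter) {
  new("ScoreSet", genuine = as.numeric(genuine),
      imposter = as.numeric(imposter))
}

#' All-pairs match scores for a labeled distance matrix
#'
#' Splits the upper triangle of a symmetric pairwise distance matrix into
#' genuine (same class) and imposter (different class) scores.
#'
#' @param d symmetric numeric matrix of pairwise distances.
#' @param classes class label per row of \code{d}.
#' @return a \linkS4class{ScoreSet}.
#' @export
splitScores <- function(d, classes) {
  n <- nrow(d)
  if (length(classes) != n) stop("splitScores: label length mismatch")
  ut <- upper.tri(d)
  same <- outer(classes, classes, "==")
  scoreSet(d[ut & same], d[ut & !same])
}

#' Equal error rate from a score set
#'
#' Sweeps the threshold over the pooled distinct score values;
#' \code{FAR(t)} is the fraction of imposter distances <= t and
#' \code{FRR(t)} the fraction of genuine distances > t. The EER is
#' \code{(FAR + FRR) / 2} at the threshold minimizing \code{|FAR - FRR|}
#' (smallest such threshold on ties), in percent.
#'
#' @param s a \linkS4class{ScoreSet} with both lists non-empty.
#' @return an \linkS4class{EERResult} with the full ROC table.
#' @export
computeEER <- function(s) {
  gen <- s@genuine; imp <- s@imposter
  if (length(gen) == 0L || length(imp) == 0L)
    stop("computeEER: both genuine and imposter scores are required")
  thr <- sort(unique(c(gen, imp)))
  ng <- length(gen); ni <- length(imp)
  # counts via findInterval on sorted scores: #(x <= t)
  gs <- sort(gen); is <- sort(imp)
  far <- findInterval(thr, is) / ni
  frr <- 1 - findInterval(thr, gs) / ng
  d <- abs(far - frr)
  # smallest threshold among (near-)ties, robust to 1-ulp differences
  i <- which(d <= min(d) + 1e-12)[1L]
  roc <- data.frame(threshold = thr, FAR = 100 * far, FRR = 100 * frr,
                    GAR = 100 * (1 - frr))
  new("EERResult", eer = 100 * (far[i] + frr[i]) / 2, threshold = thr[i],
      roc = roc)
}

#' Write a ScoreSet as a two-column CSV
#'
#' Columns: label (genuine/imposter) and distance.
#'
#' @param s a \linkS4class{ScoreSet}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeScoreSet <- function(s, path) {
  df <- data.frame(
    label = rep(c("genuine", "imposter"),
                c(length(s@genuine), length(s@imposter))),
    distance = c(s@genuine, s@imposter))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a ScoreSet from CSV
#'
#' @param path CSV written by \code{\link{writeScoreSet}}.
#' @return a \linkS4class{ScoreSet}.
#' @export
readScoreSet <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("label", "distance") %in% names(df)))
    stop("readScoreSet: need columns label, distance in ", path)
  scoreSet(df$distance[df$label == "genuine"],
           df$distance[df$label == "imposter"])
}
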