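## End-to-end orchestration: configuration, the enhancement chain
## (region detection -> Gabor -> Retinex -> fuzzy fusion), feature
## extraction, and gallery evaluation, plus the command entry points the
## CLI script wraps.

#' Pipeline configuration
#'
#' Flat key list covering every stage; unknown keys are rejected. The
#' defaults are the configuration with the best verification accuracy on
#' the high-resolution database convention: Retinex sigma 20, fusion by the
#' Min rule with LOM defuzzification, LBP features.
#'
#' @param ... overrides of the default keys, e.g.
#'   \code{veinConfig(fusion.rule = "max", retinex.sigma = 15)}. Keys:
#'   \code{roi.profile} (custom/database_I/database_II), \code{roi.x1},
#'   \code{roi.x2}, \code{roi.mask_width}, \code{roi.mask_height},
#'   \code{roi.vertical_inset}, \code{gabor.f}, \code{gabor.sigma_x},
#'   \code{gabor.sigma_y}, \code{gabor.kernel_size} (NULL = automatic),
#'   \code{retinex.sigma}, \code{retinex.epsilon}, \code{fusion.window},
#'   \code{fusion.rule} (min/max), \code{fusion.defuzzifier}
#'   (fom/lom/mom/meom/cog), \code{features} (lbp/haar/daubechies).
#' @return validated named list.
#' @export
veinConfig <- function(...) {
  cfg <- list(
    roi.profile = "custom", roi.x1 = 10L, roi.x2 = 10L,
    roi.mask_width = 20L, roi.mask_height = 4L, roi.vertical_inset = 15L,
    gabor.f = 0.05, gabor.sigma_x = 9.53, gabor.sigma_y = 9.53,
    gabor.kernel_size = NULL,
    retinex.sigma = 20, retinex.epsilon = 1,
    fusion.window = 21L, fusion.rule = "min", fusion.defuzzifier = "lom",
    features = "lbp")
  ov <- list(...)
  bad <- setdiff(names(ov), names(cfg))
  if (length(bad))
    stop("veinConfig: unknown key(s): ", paste(bad, collapse = ", "))
  cfg[names(ov)] <- ov
  if (!cfg$fusion.rule %in% c("min", "max"))
    stop("veinConfig: fusion.rule must be 'min' or 'max'")
  if (!cfg$fusion.defuzzifier %in% c("fom", "lom", "mom", "meom", "cog"))
    stop("veinConfig: invalid fusion.defuzzifier")
  if (!cfg$features %in% c("lbp", "haar", "daubechies"))
    stop("veinConfig: features must be lbp, haar or daubechies")
  if (!cfg$roi.profile %in% c("custom", "database_I", "database_II"))
    stop("veinConfig: invalid roi.profile")
  cfg
}

#' Enhance one finger-vein image
#'
#' The full chain: boundary detection, region cropping, four-directional
#' Gabor filtering, single-scale Retinex, and pixel-wise fuzzy fusion.
#'
#' @param img numeric matrix in [0, 255] (a full captured frame).
#' @param cfg configuration from \code{\link{veinConfig}}.
#' @return list with \code{enhanced} (fused image, cropped coordinates),
#'   \code{gabor}, \code{retinex}, \code{weights} (Gabor weight map) and
#'   \code{roi} (boundaries in cropped coordinates).
#' @export
enhanceImage <- function(img, cfg = veinConfig()) {
  roi <- detectBoundaries(img, maskW = cfg$roi.mask_width,
                          maskH = cfg$roi.mask_height,
                          x1 = cfg$roi.x1, x2 = cfg$roi.x2)
  cr <- cropRoi(img, roi, profile = cfg$roi.profile,
                verticalInset = cfg$roi.vertical_inset)
  gp <- gaborParams(f = cfg$gabor.f, sigmaX = cfg$gabor.sigma_x,
                    sigmaY = cfg$gabor.sigma_y,
                    kernelSize = cfg$gabor.kernel_size)
  gab <- applyGaborBank(cr$image, gp)
  ret <- ssr(cr$image, retinexParams(cfg$retinex.sigma, cfg$retinex.epsilon))
  fused <- fuseImages(gab, ret, window = cfg$fusion.window,
                      rule = cfg$fusion.rule,
                      method = cfg$fusion.defuzzifier)
  list(enhanced = fused$image, gabor = gab, retinex = ret,
       weights = fused$weights, roi = cr$roi)
}

#' Extract matching features from an enhanced region
#'
#' Size-normalizes to 150 x 60, downsamples to 50 x 20, and extracts either
#' the LBP vein code or a raw (unnormalized) 128-vector of wavelet-packet
#' statistics; wavelet vectors are meant to be normalized per feature
#' across the gallery with \code{\link{normalizeFeatureMatrix}}.
#'
#' @param img enhanced image in cropped coordinates.
#' @param roi matching \linkS4class{FingerROI} in the same coordinates.
#' @param backend \code{"lbp"}, \code{"haar"} or \code{"daubechies"}.
#' @return a \linkS4class{VeinCode} for lbp, else a numeric 128-vector.
#' @export
extractFeatures <- function(img, roi, backend = c("lbp", "haar",
                                                  "daubechies")) {
  backend <- match.arg(backend)
  down <- downsample3x3(normalizeSize(img, roi))
  if (backend == "lbp") lbpCode(down)
  else waveletFeatures(down, backend, normalize = FALSE)
}

#' Evaluate verification accuracy on a gallery
#'
#' Enhances every image (optionally skipping enhancement to obtain the
#' unenhanced baseline), extracts features, computes all-pairs distances
#' (Hamming for LBP, RMS Euclidean for wavelets after per-feature gallery
#' normalization), and sweeps the EER.
#'
#' @param gallery a \linkS4class{VeinGallery}.
#' @param cfg configuration from \code{\link{veinConfig}}.
#' @param enhance run the enhancement chain (FALSE = crop + features only).
#' @return list with \code{eer} (an \linkS4class{EERResult}), \code{scores}
#'   (a \linkS4class{ScoreSet}) and \code{pairs} (the authentic/imposter
#'   counts).
#' @export
evaluateGallery <- function(gallery, cfg = veinConfig(), enhance = TRUE) {
  feats <- lapply(gallery@images, function(li) {
    if (enhance) {
      e <- enhanceImage(li@image, cfg)
      extractFeatures(e$enhanced, e$roi, cfg$features)
    } else {
      roi <- detectBoundaries(li@image, maskW = cfg$roi.mask_width,
                              maskH = cfg$roi.mask_height,
                              x1 = cfg$roi.x1, x2 = cfg$roi.x2)
      cr <- cropRoi(li@image, roi, profile = cfg$roi.profile,
                    verticalInset = cfg$roi.vertical_inset)
      extractFeatures(cr$image, cr$roi, cfg$features)
    }
  })
  d <- pairwiseDistances(feats, cfg$features)
  scores <- splitScores(d, gallery@classId)
  perClass <- as.integer(table(gallery@classId))
  list(eer = computeEER(scores), scores = scores,
       pairs = c(authentic = length(scores@genuine),
                 imposter = length(scores@imposter)))
}

pairwiseDistances <- function(feats, backend) {
  n <- length(feats)
  if (backend == "lbp") {
    B <- do.call(rbind, lapply(feats, function(c) c@bits))
    nb <- ncol(B)
    # HD(a, b) = (a (1-b)' + (1-a) b') / N, vectorized over all pairs
    d <- (B %*% t(1 - B) + (1 - B) %*% t(B)) / nb
  } else {
    M <- normalizeFeatureMatrix(do.call(rbind, feats))
    sq <- rowSums(M^2)
    d2 <- outer(sq, sq, "+") - 2 * M %*% t(M)
    d <- sqrt(pmax(d2, 0) / ncol(M))
  }
  d
}

## ---- command entry points ------------------------------------------------

#' Enhance images from a path or directory
#'
#' Reads each input image, runs \code{\link{enhanceImage}}, and writes the
#' enhanced region (and optionally the weight map) next to \code{outDir}.
#' Per-file failures are reported and skipped; the call errors only if
#' every file fails.
#'
#' @param input one image path or a directory of images.
#' @param outDir output directory.
#' @param cfg configuration from \code{\link{veinConfig}}.
#' @param writeWeights also write the Gabor weight map as a PNG.
#' @return character vector of output paths, invisibly.
#' @export
cmdEnhance <- function(input, outDir, cfg = veinConfig(),
                       writeWeights = FALSE) {
  paths <- if (dir.exists(input))
    list.files(input, pattern = "\\.(pgm|png|tif|tiff)$", full.names = TRUE,
               ignore.case = TRUE)
  else input
  if (length(paths) == 0L)
    stop("cmdEnhance: no input images found in ", input)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  outs <- character(0)
  for (p in paths) {
    res <- tryCatch({
      t0 <- proc.time()[["elapsed"]]
      e <- enhanceImage(readGray(p), cfg)
      stem <- tools::file_path_sans_ext(basename(p))
      out <- file.path(outDir, paste0(stem, "_enhanced.png"))
      writeGray(e$enhanced, out)
      if (writeWeights)
        writeGray(e$weights * 255,
                  file.path(outDir, paste0(stem, "_weights.png")))
      message(sprintf("enhanced %s (%.2f s)", basename(p),
                      proc.time()[["elapsed"]] - t0))
      out
    }, error = function(err) {
      message("skipping ", p, ": ", conditionMessage(err))
      NULL
    })
    if (!is.null(res)) outs <- c(outs, res)
  }
  if (length(outs) == 0L) stop("cmdEnhance: all inputs failed")
  invisible(outs)
}

#' Evaluate a gallery manifest
#'
#' Reads a manifest CSV (columns path, class_id, sample_id), runs the full
#' pipeline on every image, and writes the score set and ROC table as CSVs
#' into \code{outDir}. The EER is printed to 4 decimal places.
#'
#' @param manifest manifest CSV path.
#' @param outDir output directory.
#' @param cfg configuration from \code{\link{veinConfig}}.
#' @param enhance run the enhancement chain.
#' @return the \code{\link{evaluateGallery}} result, invisibly.
#' @export
cmdEvaluate <- function(manifest, outDir, cfg = veinConfig(),
                        enhance = TRUE) {
  df <- tryCatch(utils::read.csv(manifest),
                 error = function(e) stop("cmdEvaluate: cannot parse ",
                                          manifest, ": ",
                                          conditionMessage(e)))
  need <- c("path", "class_id", "sample_id")
  if (!all(need %in% names(df)))
    stop("cmdEvaluate: manifest must have columns ",
         paste(need, collapse = ", "))
  bad <- which(!file.exists(df$path))
  if (length(bad))
    stop("cmdEvaluate: missing image at manifest line ", bad[1] + 1L, ": ",
         df$path[bad[1]])
  if (length(unique(df$class_id)) < 2L)
    stop("cmdEvaluate: need at least 2 classes")
  imgs <- mapply(function(p, cl, sm) {
    m <- readGray(p)   # mask is unused during evaluation
    new("LabeledVeinImage", image = m,
        mask = matrix(FALSE, nrow(m), ncol(m)),
        classId = as.integer(cl), sampleId = as.integer(sm))
  }, df$path, df$class_id, df$sample_id, SIMPLIFY = FALSE)
  gallery <- new("VeinGallery", images = imgs,
                 classId = as.integer(df$class_id),
                 sampleId = as.integer(df$sample_id), spec = list())
  res <- evaluateGallery(gallery, cfg, enhance = enhance)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  writeScoreSet(res$scores, file.path(outDir, "scores.csv"))
  utils::write.csv(rocCurve(res$eer), file.path(outDir, "roc.csv"),
                   row.names = FALSE)
  cat(sprintf("EER = %.4f%%\n", eer(res$eer)))
  invisible(res)
}
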