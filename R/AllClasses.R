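#' @import methods
NULL

#' Finger region-of-interest boundaries
#'
#' Per-column upper and lower finger boundary rows found by template
#' matching, together with the horizontal crop limits \code{x1} (columns
#' dropped on the left) and \code{x2} (columns dropped on the right).
#' Row and column indices are 1-based.
#'
#' @slot upperY integer vector, one entry per image column: first finger row.
#' @slot lowerY integer vector, one entry per image column: last finger row.
#' @slot x1 integer, number of columns discarded at the left edge.
#' @slot x2 integer, number of columns discarded at the right edge.
#' @slot degenerate logical, TRUE when template matching found no edge
#'   signal (e.g. a uniform image) and the boundaries are tie-broken defaults.
#' @exportClass FingerROI
setClass("FingerROI",
  representation(upperY = "integer", lowerY = "integer",
                 x1 = "integer", x2 = "integer", degenerate = "logical"),
  validity = function(object) {
    if (length(object@upperY) != length(object@lowerY))
      return("upperY and lowerY must have equal length")
    if (object@x1 < 0L || object@x2 < 0L)
      return("x1 and x2 must be non-negative")
    w <- length(object@upperY)
    if (object@x1 + object@x2 >= w)
      return("x1 + x2 must be smaller than the image width")
    keep <- seq.int(object@x1 + 1L, w - object@x2)
    if (!object@degenerate && any(object@upperY[keep] >= object@lowerY[keep]))
      return("upperY must lie above lowerY in every retained column")
    TRUE
  })

#' Binary vein code
#'
#' Fixed-length binary code produced by the local binary pattern (LBP)
#' operator on a 50 x 20 normalized vein image: 8 bits for each of the
#' 48 x 18 interior pixels, 6,912 bits in total.
#'
#' @slot bits integer vector of 0/1 values.
#' @slot width,height integer, interior code grid size (48 x 18).
#' @slot bitsPerPixel integer, bits per code pixel (8).
#' @exportClass VeinCode
setClass("VeinCode",
  representation(bits = "integer", width = "integer", height = "integer",
                 bitsPerPixel = "integer"),
  validity = function(object) {
    n <- object@width * object@height * object@bitsPerPixel
    if (length(object@bits) != n)
      return(sprintf("bits must have length %d (= %d x %d x %d)",
                     n, object@bitsPerPixel, object@width, object@height))
    if (!all(object@bits %in% c(0L, 1L))) return("bits must be 0/1")
    TRUE
  })

#' Labeled genuine/imposter match scores
#'
#' @slot genuine numeric, distances between samples of the same finger.
#' @slot imposter numeric, distances between samples of different fingers.
#' @exportClass ScoreSet
setClass("ScoreSet",
  representation(genuine = "numeric", imposter = "numeric"),
  validity = function(object) {
    if (any(object@genuine < 0) || any(object@imposter < 0))
      return("match distances must be non-negative")
    TRUE
  })

#' Equal-error-rate result
#'
#' @slot eer numeric, equal error rate in percent.
#' @slot threshold numeric, decision threshold where FAR is closest to FRR.
#' @slot roc data.frame with columns threshold, FAR, FRR, GAR (percent);
#'   GAR = 100 - FRR.
#' @exportClass EERResult
setClass("EERResult",
  representation(eer = "numeric", threshold = "numeric", roc = "data.frame"),
  validity = function(object) {
    if (object@eer < 0 || object@eer > 100) return("eer must be in [0, 100]")
    need <- c("threshold", "FAR", "FRR", "GAR")
    if (!all(need %in% names(object@roc)))
      return("roc must have columns threshold, FAR, FRR, GAR")
    TRUE
  })

#' Synthetic labeled vein image
#'
#' @slot image numeric matrix in [0, 255], the rendered NIR-like image.
#' @slot mask logical matrix, TRUE on ground-truth vein pixels.
#' @slot classId,sampleId integer identifiers.
#' @exportClass LabeledVeinImage
setClass("LabeledVeinImage",
  representation(image = "matrix", mask = "matrix",
                 classId = "integer", sampleId = "integer"),
  validity = function(object) {
    if (!identical(dim(object@image), dim(object@mask)))
      return("mask must have the same shape as the image")
    TRUE
  })

#' Gallery of synthetic vein images
#'
#' @slot images list of LabeledVeinImage objects.
#' @slot classId,sampleId integer vectors parallel to \code{images}.
#' @slot spec list, the generator settings used.
#' @exportClass VeinGallery
setClass("VeinGallery",
  representation(images = "list", classId = "integer",
                 sampleId = "integer", spec = "list"),
  validity = function(object) {
    n <- length(object@images)
    if (length(object@classId) != n || length(object@sampleId) != n)
      return("classId and sampleId must parallel images")
    TRUE
  })

setMethod("show", "FingerROI", function(object) {
  w <- length(object@upperY)
  keep <- seq.int(object@x1 + 1L, w - object@x2)
  cat(sprintf("FingerROI: %d columns, retaining [%d, %d] (x1=%d, x2=%d)\n",
              w, object@x1 + 1L, w - object@x2, object@x1, object@x2))
  cat(sprintf("  upper boundary rows in [%d, %d], lower in [%d, %d]%s\n",
              min(object@upperY[keep]), max(object@upperY[keep]),
              min(object@lowerY[keep]), max(object@lowerY[keep]),
              if (object@degenerate) " [degenerate]" else ""))
})

setMethod("show", "VeinCode", function(object) {
  cat(sprintf("VeinCode: %d bits (%d x %d x %d), density %.3f\n",
              length(object@bits), object@bitsPerPixel, object@width,
              object@height, mean(object@bits)))
})

setMethod("show", "ScoreSet", function(object) {
  cat(sprintf("ScoreSet: %d genuine, %d imposter distances\n",
              length(object@genuine), length(object@imposter)))
})

setMethod("show", "EERResult", function(object) {
  cat(sprintf("EERResult: EER = %.4f%% at threshold %.6g (%d ROC points)\n",
              object@eer, object@threshold, nrow(object@roc)))
})

setMethod("show", "LabeledVeinImage", function(object) {
  cat(sprintf("LabeledVeinImage: class %d sample %d, %d x %d, %.1f%% vein\n",
              object@classId, object@sampleId, nrow(object@image),
              ncol(object@image), 100 * mean(object@mask)))
})

setMethod("show", "VeinGallery", function(object) {
  cat(sprintf("VeinGallery: %d images, %d classes\n",
              length(object@images), length(unique(object@classId))))
})

# ---- accessors ----

#' @describeIn FingerROI-accessors first finger row per column
#' @export
upperBoundary <- function(roi) roi@upperY

#' Accessors for FingerROI, ScoreSet, EERResult and VeinCode
#'
#' Small read-only accessors so user code never touches slots directly.
#'
#' @param roi a \linkS4class{FingerROI}.
#' @param code a \linkS4class{VeinCode}.
#' @param scores a \linkS4class{ScoreSet}.
#' @param result an \linkS4class{EERResult}.
#' @name FingerROI-accessors
#' @export
lowerBoundary <- function(roi) roi@lowerY

#' @describeIn FingerROI-accessors horizontal crop limits c(x1, x2)
#' @export
cropLimits <- function(roi) c(x1 = roi@x1, x2 = roi@x2)

#' @describeIn FingerROI-accessors raw 0/1 bit vector of a VeinCode
#' @export
veinBits <- function(code) code@bits

#' @describeIn FingerROI-accessors genuine distances of a ScoreSet
#' @export
genuineScores <- function(scores) scores@genuine

#' @describeIn FingerROI-accessors imposter distances of a ScoreSet
#' @export
imposterScores <- function(scores) scores@imposter

#' @describeIn FingerROI-accessors equal error rate (percent)
#' @export
eer <- function(result) result@eer

#' @describeIn FingerROI-accessors ROC table (threshold, FAR, FRR, GAR)
#' @export
rocCurve <- function(result) result@roc

#' @describeIn FingerROI-accessors list of images in a VeinGallery
#' @export
galleryImages <- function(gallery) gallery@images

#' @describeIn FingerROI-accessors class labels of a VeinGallery
#' @export
galleryClasses <- function(gallery) gallery@classId
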