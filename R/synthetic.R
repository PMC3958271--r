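## Seeded generator of synthetic NIR finger-vein images with ground-truth
## masks. The model: a bright finger band between dark background margins,
## crossed by a few dark curvilinear vein tracks (smoothed random walks of
## bounded curvature, widths 3-10 px), degraded by a smooth illumination
## gradient, Gaussian blur and additive Gaussian noise -- the degradation
## factors that make real transillumination imagery hard (skin scattering,
## optical and motion blur). Class geometry is drawn from a class-level
## seed; per-sample jitter, illumination and noise from a sample-level
## seed, so galleries are reproducible item-wise.

#' Synthetic vein image specification
#'
#' Defaults follow the 320 x 240 low-resolution imaging convention.
#'
#' @param width,height image size in pixels.
#' @param fingerMargin dark background band top and bottom, pixels.
#' @param nVeins number of vein tracks.
#' @param veinWidthRange c(min, max) vein width in pixels. The default 6-10
#'   matches subcutaneous veins at the 320 x 240 imaging scale (about 0.1
#'   mm/pixel), the scale the enhancement filters are designed for.
#' @param veinIntensityDrop gray levels a vein sits below the skin; veins in
#'   transillumination imagery are low-contrast, so the default (40) is well
#'   below the skin level.
#' @param skinLevel gray level of the lit finger tissue.
#' @param backgroundLevel gray level of the background bands.
#' @param edgeWidth pixels over which the finger silhouette rolls off from
#'   background to skin (raised-cosine shoulder); a transilluminated finger
#'   glows, so its outline is never a hard step.
#' @param illuminationGradient gray-level span of the smooth horizontal
#'   illumination ramp.
#' @param blurSigma Gaussian blur scale, pixels (0 disables); skin
#'   scattering and optics blur strongly at this resolution.
#' @param noiseSigma additive Gaussian noise STD, gray levels (0 disables).
#' @param classJitter per-sample geometric perturbation magnitude, pixels
#'   (translation; a tilt of the same magnitude end-to-end).
#' @param seed integer master seed.
#' @return validated list of generator settings.
#' @export
syntheticSpec <- function(width = 320L, height = 240L, fingerMargin = 40L,
                          nVeins = 5L, veinWidthRange = c(6, 10),
                          veinIntensityDrop = 40, skinLevel = 180,
                          backgroundLevel = 30, edgeWidth = 12,
                          illuminationGradient = 30,
                          blurSigma = 3, noiseSigma = 3, classJitter = 2,
                          seed = 1L) {
  if (any(c(fingerMargin, nVeins, veinIntensityDrop, illuminationGradient,
            blurSigma, noiseSigma, classJitter) < 0))
    stop("syntheticSpec: magnitudes must be non-negative")
  if (veinIntensityDrop >= skinLevel)
    stop("syntheticSpec: veinIntensityDrop must be below skinLevel")
  if (max(veinWidthRange) >= height - 2 * fingerMargin)
    stop("syntheticSpec: vein width exceeds the finger band")
  list(width = as.integer(width), height = as.integer(height),
       fingerMargin = as.integer(fingerMargin), nVeins = as.integer(nVeins),
       veinWidthRange = veinWidthRange,
       veinIntensityDrop = veinIntensityDrop, skinLevel = skinLevel,
       backgroundLevel = backgroundLevel, edgeWidth = edgeWidth,
       illuminationGradient = illuminationGradient, blurSigma = blurSigma,
       noiseSigma = noiseSigma, classJitter = classJitter,
       seed = as.integer(seed))
}

subSeed <- function(seed, classId, sampleId = 0L) {
  # deterministic 31-bit sub-seed per (class, sample)
  as.integer((as.double(seed) * 7919 + classId * 104729 +
                sampleId * 130363) %% 2147483647)
}

# smoothed random-walk vein centerlines and widths for one class
classGeometry <- function(spec, classId) {
  set.seed(subSeed(spec$seed, classId))
  w <- spec$width; h <- spec$height
  band <- c(spec$fingerMargin + max(spec$veinWidthRange),
            h - spec$fingerMargin - max(spec$veinWidthRange))
  lapply(seq_len(spec$nVeins), function(v) {
    start <- stats::runif(1, band[1], band[2])
    # gentle drift: finger veins run nearly parallel to the finger axis
    steps <- stats::rnorm(w, 0, 0.4)
    y <- start + cumsum(steps)
    y <- stats::filter(c(rep(y[1], 20), y, rep(y[w], 20)),
                       rep(1 / 41, 41), sides = 2)[21:(20 + w)]
    list(center = pmin(pmax(as.numeric(y), band[1]), band[2]),
         width = stats::runif(1, spec$veinWidthRange[1],
                              spec$veinWidthRange[2]))
  })
}

#' Generate one labeled synthetic vein image
#'
#' @param spec settings from \code{\link{syntheticSpec}}.
#' @param classId,sampleId identifiers; the vein geometry depends only on
#'   \code{classId}, the jitter/illumination/noise draws also on
#'   \code{sampleId}.
#' @return a \linkS4class{LabeledVeinImage}.
#' @export
generateImage <- function(spec = syntheticSpec(), classId = 1L,
                          sampleId = 1L) {
  geom <- classGeometry(spec, classId)
  set.seed(subSeed(spec$seed, classId, sampleId))
  w <- spec$width; h <- spec$height
  # smooth silhouette: raised-cosine shoulder between background and skin
  rowIdx <- seq_len(h)
  shoulder <- function(d) ifelse(d <= 0, 0,
    ifelse(d >= spec$edgeWidth, 1, 0.5 - 0.5 * cos(pi * d / spec$edgeWidth)))
  prof <- shoulder(rowIdx - spec$fingerMargin) *
    shoulder(h - spec$fingerMargin + 1 - rowIdx)
  img <- matrix(spec$backgroundLevel +
                  (spec$skinLevel - spec$backgroundLevel) * prof, h, w)
  band <- seq.int(spec$fingerMargin + 1L, h - spec$fingerMargin)
  mask <- matrix(FALSE, h, w)

  dy <- if (spec$classJitter > 0)
    stats::runif(1, -spec$classJitter, spec$classJitter) else 0
  tilt <- if (spec$classJitter > 0)
    stats::runif(1, -spec$classJitter, spec$classJitter) else 0
  xs <- seq_len(w)
  tiltLine <- tilt * (xs - (w + 1) / 2) / w

  rows <- matrix(seq_len(h), h, w)
  for (vein in geom) {
    center <- matrix(vein$center + dy + tiltLine, h, w, byrow = TRUE)
    d <- abs(rows - center)
    halfw <- vein$width / 2
    # trapezoidal cross-profile: full drop inside, 1-px linear shoulder
    frac <- pmin(pmax(halfw + 0.5 - d, 0), 1)
    img <- img - spec$veinIntensityDrop * frac *
      (rows >= band[1] & rows <= band[length(band)])
    mask <- mask | (frac >= 0.5 &
                      rows >= band[1] & rows <= band[length(band)])
  }

  if (spec$illuminationGradient > 0) {
    u <- stats::runif(1, 0.7, 1)
    ramp <- spec$illuminationGradient * u * ((xs - 1) / (w - 1) - 0.5)
    img[band, ] <- img[band, ] + matrix(ramp, length(band), w, byrow = TRUE)
  }
  if (spec$blurSigma > 0)
    img <- convolve2d(img, gaussianKernel(spec$blurSigma))
  if (spec$noiseSigma > 0)
    img <- img + matrix(stats::rnorm(h * w, 0, spec$noiseSigma), h, w)
  img <- pmin(pmax(img, 0), 255)

  new("LabeledVeinImage", image = img, mask = mask,
      classId = as.integer(classId), sampleId = as.integer(sampleId))
}

#' Generate a gallery of synthetic vein images
#'
#' Each class keeps a fixed vein geometry; samples within a class differ by
#' the jitter, illumination and noise draws.
#'
#' @param spec settings from \code{\link{syntheticSpec}}.
#' @param classes number of distinct fingers.
#' @param perClass samples per finger.
#' @return a \linkS4class{VeinGallery}.
#' @export
generateGallery <- function(spec = syntheticSpec(), classes = 2L,
                            perClass = 2L) {
  ids <- expand.grid(sampleId = seq_len(perClass),
                     classId = seq_len(classes))
  imgs <- mapply(function(cl, sm) generateImage(spec, cl, sm),
                 ids$classId, ids$sampleId, SIMPLIFY = FALSE)
  new("VeinGallery", images = imgs, classId = as.integer(ids$classId),
      sampleId = as.integer(ids$sampleId), spec = spec)
}

#' Write a gallery to disk as PGM images plus a manifest
#'
#' Writes one PGM per image, one PNG per ground-truth mask, and a manifest
#' CSV with columns path, class_id, sample_id.
#'
#' @param gallery a \linkS4class{VeinGallery}.
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
writeGallery <- function(gallery, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(gallery@images, function(li) {
    stem <- sprintf("class%03d_sample%02d", li@classId, li@sampleId)
    p <- file.path(dir, paste0(stem, ".pgm"))
    writeGray(li@image, p)
    png::writePNG(li@mask * 1, file.path(dir, paste0(stem, "_mask.png")))
    data.frame(path = p, class_id = li@classId, sample_id = li@sampleId)
  })
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(do.call(rbind, rows), manifest, row.names = FALSE)
  invisible(manifest)
}
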