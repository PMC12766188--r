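#' @import methods
NULL

## Pixel arrays are numeric with dim c(h, w) (grayscale) or c(h, w, channels);
## masks are logical h x w matrices; boxes are 0-based COCO [x, y, w, h].

#' Instance: one labelled object in an image
#'
#' A ground-truth object: a tight bounding box, a full-frame binary mask and a
#' category. Boxes use the COCO convention `[x, y, w, h]` with 0-based pixel
#' coordinates; the box is always the tight bounding box of the mask (geometric
#' transforms may introduce up to ~1 px of resampling slack, which the validity
#' check tolerates).
#'
#' @slot box numeric(4), `[x, y, w, h]`, 0-based pixels.
#' @slot mask logical matrix congruent with the parent image.
#' @slot classId integer category id (single category "hRS" = 1 here).
#' @slot instanceId integer, unique within its image.
#' @export
setClass("Instance", representation(
  box = "numeric", mask = "matrix", classId = "integer", instanceId = "integer"
))

setValidity("Instance", function(object) {
  msg <- character()
  if (length(object@box) != 4L) msg <- c(msg, "box must have 4 elements [x, y, w, h]")
  if (!is.logical(object@mask)) msg <- c(msg, "mask must be a logical matrix")
  if (length(object@box) == 4L) {
    if (object@box[3L] <= 0 || object@box[4L] <= 0)
      msg <- c(msg, "box width and height must be positive")
  }
  if (is.logical(object@mask)) {
    if (!any(object@mask)) msg <- c(msg, "mask must have at least one foreground pixel")
    else if (length(object@box) == 4L) {
      tb <- tightBox(object@mask)
      if (max(abs(tb - object@box)) > 2)  # resampling slack
        msg <- c(msg, "box is not the tight bounding box of the mask (>2 px off)")
    }
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn Instance-class constructor; `box = NULL` derives the tight box
#'   from the mask.
#' @param mask logical (or coercible) matrix with at least one `TRUE` pixel.
#' @param box optional numeric(4) `[x, y, w, h]`; computed from `mask` if `NULL`.
#' @param classId,instanceId integer ids.
#' @export
Instance <- function(mask, box = NULL, classId = 1L, instanceId = 1L) {
  mask <- asMask(mask)
  if (is.null(box)) box <- tightBox(mask)
  new("Instance", box = as.numeric(box), mask = mask,
      classId = as.integer(classId), instanceId = as.integer(instanceId))
}

#' Prediction: one detector output
#'
#' A detector hypothesis: box, binary mask, confidence score and the id of the
#' image it refers to. Soft (real-valued) masks are binarised at construction
#' with `maskBinarizeThreshold` before any overlap computation.
#'
#' @slot box numeric(4) `[x, y, w, h]`, 0-based pixels.
#' @slot mask logical matrix (may be empty, i.e. all background).
#' @slot score numeric confidence in [0, 1].
#' @slot imageId integer.
#' @export
setClass("Prediction", representation(
  box = "numeric", mask = "matrix", score = "numeric", imageId = "integer"
))

setValidity("Prediction", function(object) {
  msg <- character()
  if (length(object@box) != 4L) msg <- c(msg, "box must have 4 elements")
  if (length(object@score) != 1L || object@score < 0 || object@score > 1)
    msg <- c(msg, "score must be a single value in [0, 1]")
  if (!is.logical(object@mask)) msg <- c(msg, "mask must be logical (binarized)")
  if (length(msg)) msg else TRUE
})

#' @describeIn Prediction-class constructor; real-valued masks are binarised at
#'   `maskBinarizeThreshold` (pixels strictly above the threshold become
#'   foreground); `box = NULL` derives the tight box from the binarised mask
#'   (requires a non-empty mask).
#' @param mask numeric or logical matrix.
#' @param score confidence in [0, 1].
#' @param box optional numeric(4).
#' @param imageId integer id of the image the prediction refers to.
#' @param maskBinarizeThreshold binarisation threshold for soft masks
#'   (default 0.5).
#' @export
Prediction <- function(mask, score, box = NULL, imageId = 1L,
                       maskBinarizeThreshold = 0.5) {
  if (!is.logical(mask)) {
    stopifnot(is.numeric(mask), is.matrix(mask))
    mask <- mask > maskBinarizeThreshold
  }
  if (is.null(box)) {
    if (!any(mask)) stop("cannot derive a box from an empty mask; supply `box`")
    box <- tightBox(mask)
  }
  new("Prediction", box = as.numeric(box), mask = mask,
      score = as.numeric(score), imageId = as.integer(imageId))
}

#' AnnotatedImage: pixels plus ground-truth instances
#'
#' @slot pixels numeric array, dim `c(h, w)` (grayscale) or `c(h, w, channels)`,
#'   intensities nominally in [0, 1] before colour normalisation.
#' @slot imageId integer, unique within a dataset.
#' @slot instances list of [Instance-class] objects whose masks share the
#'   image's dimensions.
#' @export
setClass("AnnotatedImage", representation(
  pixels = "array", imageId = "integer", instances = "list"
))

setValidity("AnnotatedImage", function(object) {
  msg <- character()
  d <- dim(object@pixels)
  if (!(length(d) %in% c(2L, 3L))) msg <- c(msg, "pixels must be a 2-D or 3-D array")
  for (inst in object@instances) {
    if (!is(inst, "Instance")) { msg <- c(msg, "instances must be Instance objects"); break }
    if (!identical(dim(inst@mask), d[1:2])) {
      msg <- c(msg, "every instance mask must have the image's dimensions"); break
    }
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn AnnotatedImage-class constructor.
#' @param pixels numeric matrix or 3-D array (h, w[, channels]).
#' @param imageId integer.
#' @param instances list of `Instance`.
#' @export
AnnotatedImage <- function(pixels, imageId = 1L, instances = list()) {
  if (is.matrix(pixels)) pixels <- array(pixels, dim = dim(pixels))
  new("AnnotatedImage", pixels = pixels, imageId = as.integer(imageId),
      instances = instances)
}

#' DatasetSplit: train/validation/test assignment at image granularity
#'
#' Sizes are realised *instance* counts; the assignment maps whole images to
#' subsets (images are never divided between subsets).
#'
#' @slot trainSize,valSize,testSize integer instance counts.
#' @slot assignment data.frame with columns `imageId`, `subset`
#'   (one of "train", "val", "test") and `nInstances`.
#' @export
setClass("DatasetSplit", representation(
  trainSize = "integer", valSize = "integer", testSize = "integer",
  assignment = "data.frame"
))

setValidity("DatasetSplit", function(object) {
  a <- object@assignment
  msg <- character()
  if (!all(c("imageId", "subset", "nInstances") %in% names(a)))
    msg <- c(msg, "assignment needs columns imageId, subset, nInstances")
  else {
    if (!all(a$subset %in% c("train", "val", "test")))
      msg <- c(msg, "subset labels must be train/val/test")
    if (anyDuplicated(a$imageId)) msg <- c(msg, "each image assigned exactly once")
    tot <- object@trainSize + object@valSize + object@testSize
    if (tot != sum(a$nInstances)) msg <- c(msg, "sizes must sum to the total instance count")
  }
  if (length(msg)) msg else TRUE
})

#' RegionCrop: one harvested confusing region
#'
#' A tight crop of image pixels plus its binary mask, harvested from detector
#' output at some training step. `zooLabel` records which update rule produced
#' it: `"eq1_zoo"` (low-confidence detector hits intersected with ground truth
#' -- pixel subsets of true objects) or `"eq2_zoo"` (high-confidence detector
#' hits outside all ground truth -- confusing background).
#'
#' @slot pixels numeric patch (h, w[, channels]), raw pre-normalisation
#'   intensities.
#' @slot mask logical patch congruent with `pixels`.
#' @slot sourceImageId integer image of origin.
#' @slot sourceScore numeric confidence of the originating prediction.
#' @slot zooLabel character, `"eq1_zoo"` or `"eq2_zoo"`.
#' @slot entryStep integer training-step counter at harvest time.
#' @export
setClass("RegionCrop", representation(
  pixels = "array", mask = "matrix", sourceImageId = "integer",
  sourceScore = "numeric", zooLabel = "character", entryStep = "integer"
))

setValidity("RegionCrop", function(object) {
  msg <- character()
  if (!any(object@mask)) msg <- c(msg, "crop mask must be non-empty")
  if (!identical(dim(object@mask), dim(object@pixels)[1:2]))
    msg <- c(msg, "patch dimensions must equal mask dimensions")
  if (!object@zooLabel %in% c("eq1_zoo", "eq2_zoo"))
    msg <- c(msg, "zooLabel must be 'eq1_zoo' or 'eq2_zoo'")
  if (length(msg)) msg else TRUE
})

#' @describeIn RegionCrop-class constructor.
#' @param pixels,mask,sourceImageId,sourceScore,zooLabel,entryStep see slots.
#' @export
RegionCrop <- function(pixels, mask, sourceImageId, sourceScore, zooLabel,
                       entryStep = 0L) {
  if (is.matrix(pixels)) pixels <- array(pixels, dim = dim(pixels))
  new("RegionCrop", pixels = pixels, mask = asMask(mask),
      sourceImageId = as.integer(sourceImageId),
      sourceScore = as.numeric(sourceScore), zooLabel = zooLabel,
      entryStep = as.integer(entryStep))
}

#' RegionZoo: bounded FIFO collection of harvested regions
#'
#' Entries are kept in entry order (front = oldest). When an update would
#' exceed `capacity`, the first-entered element is evicted, so the zoo always
#' holds the most recent `capacity` crops.
#'
#' @slot entries list of [RegionCrop-class], ordered by `entryStep` ascending.
#' @slot capacity integer maximum size T (default 10).
#' @export
setClass("RegionZoo", representation(entries = "list", capacity = "integer"))

setValidity("RegionZoo", function(object) {
  msg <- character()
  if (object@capacity < 1L) msg <- c(msg, "capacity must be >= 1")
  if (length(object@entries) > object@capacity)
    msg <- c(msg, "zoo size exceeds capacity")
  steps <- vapply(object@entries, function(e) e@entryStep, integer(1))
  if (is.unsorted(steps)) msg <- c(msg, "entries must be ordered by entryStep")
  if (length(msg)) msg else TRUE
})

#' @describeIn RegionZoo-class constructor for an empty zoo.
#' @param capacity maximum number of stored crops (default 10).
#' @param entries initial list of `RegionCrop`.
#' @export
RegionZoo <- function(capacity = 10L, entries = list()) {
  new("RegionZoo", entries = entries, capacity = as.integer(capacity))
}

#' ZooConfig: thresholds governing region harvesting
#'
#' @slot confidenceThreshold numeric c_t in [0, 1]: predictions strictly below
#'   it feed the eq1 zoo, strictly above it feed the eq2 zoo; a score exactly
#'   at the threshold enters neither.
#' @slot overlapThreshold numeric gamma in [0, 1]: a high-confidence prediction
#'   qualifies for the eq2 zoo only if its overlap ratio with every
#'   ground-truth instance is <= gamma.
#' @slot overlapMode `"intersection_over_prediction"` (fraction of the
#'   prediction explained by ground truth; default) or `"iou"`.
#' @slot capacity integer zoo capacity T (default 10).
#' @slot minCropSize integer: harvested regions whose tight crop is smaller
#'   than this on either side are discarded (default 2; 1-px slivers carry no
#'   texture).
#' @export
setClass("ZooConfig", representation(
  confidenceThreshold = "numeric", overlapThreshold = "numeric",
  overlapMode = "character", capacity = "integer", minCropSize = "integer"
))

setValidity("ZooConfig", function(object) {
  msg <- character()
  if (object@confidenceThreshold < 0 || object@confidenceThreshold > 1)
    msg <- c(msg, "confidenceThreshold must be in [0, 1]")
  if (object@overlapThreshold < 0 || object@overlapThreshold > 1)
    msg <- c(msg, "overlapThreshold must be in [0, 1]")
  if (!object@overlapMode %in% c("intersection_over_prediction", "iou"))
    msg <- c(msg, "overlapMode must be 'intersection_over_prediction' or 'iou'")
  if (object@capacity < 1L) msg <- c(msg, "capacity must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @describeIn ZooConfig-class constructor with the default thresholds
#'   (c_t = 0.5, gamma = 0.5, T = 10).
#' @param confidenceThreshold,overlapThreshold,overlapMode,capacity,minCropSize
#'   see slots.
#' @export
ZooConfig <- function(confidenceThreshold = 0.5, overlapThreshold = 0.5,
                      overlapMode = "intersection_over_prediction",
                      capacity = 10L, minCropSize = 2L) {
  new("ZooConfig", confidenceThreshold = confidenceThreshold,
      overlapThreshold = overlapThreshold, overlapMode = overlapMode,
      capacity = as.integer(capacity), minCropSize = as.integer(minCropSize))
}

#' AugmentConfig: confusion-duplicate and regional-drop parameters
#'
#' @slot p1 paste probability per zoo per image (default 0.5).
#' @slot p2 drop probability per region (default 0.5).
#' @slot dropBlockK block side k in pixels; `NA` means automatic
#'   (`max(1, floor(min(region w, h) / 4))`).
#' @slot pastesPerZoo crops sampled per triggered zoo (default 1).
#' @slot maxPlaceAttempts placement rejection attempts before skipping a paste
#'   (default 10).
#' @slot maxPasteOverlap maximum IoU a pasted footprint may have with any
#'   existing instance (default 0.3).
#' @slot blocksPerRegion number of k x k blocks zeroed per dropped region
#'   (default 1).
#' @slot featherEdges logical; feather paste edges with a 1-px Gaussian ramp
#'   instead of a hard copy (default FALSE).
#' @export
setClass("AugmentConfig", representation(
  p1 = "numeric", p2 = "numeric", dropBlockK = "numeric",
  pastesPerZoo = "integer", maxPlaceAttempts = "integer",
  maxPasteOverlap = "numeric", blocksPerRegion = "integer",
  featherEdges = "logical"
))

setValidity("AugmentConfig", function(object) {
  msg <- character()
  if (object@p1 < 0 || object@p1 > 1) msg <- c(msg, "p1 must be in [0, 1]")
  if (object@p2 < 0 || object@p2 > 1) msg <- c(msg, "p2 must be in [0, 1]")
  if (!is.na(object@dropBlockK) && object@dropBlockK < 1)
    msg <- c(msg, "dropBlockK must be >= 1 when numeric")
  if (length(msg)) msg else TRUE
})

#' @describeIn AugmentConfig-class constructor with the default probabilities
#'   p1 = p2 = 0.5.
#' @param p1,p2,dropBlockK,pastesPerZoo,maxPlaceAttempts,maxPasteOverlap,blocksPerRegion,featherEdges
#'   see slots; `dropBlockK = NA` selects the automatic region-scaled size.
#' @export
AugmentConfig <- function(p1 = 0.5, p2 = 0.5, dropBlockK = NA_real_,
                          pastesPerZoo = 1L, maxPlaceAttempts = 10L,
                          maxPasteOverlap = 0.3, blocksPerRegion = 1L,
                          featherEdges = FALSE) {
  new("AugmentConfig", p1 = p1, p2 = p2, dropBlockK = as.numeric(dropBlockK),
      pastesPerZoo = as.integer(pastesPerZoo),
      maxPlaceAttempts = as.integer(maxPlaceAttempts),
      maxPasteOverlap = maxPasteOverlap,
      blocksPerRegion = as.integer(blocksPerRegion),
      featherEdges = featherEdges)
}

#' PreprocessConfig: preprocessing and common-augmentation parameters
#'
#' @slot targetSize output side in pixels after square padding and bilinear
#'   resizing (default 1024).
#' @slot channelMean,channelStd per-channel colour-normalisation statistics;
#'   defaults (0.485, 0.456, 0.406) and (0.299, 0.224, 0.225).
#' @slot datasetMean,datasetVar pooled pixel statistics of the training subset
#'   (NA until computed with [zscoreDatasetStats()]).
#' @slot flipP per-axis flip probability (default 0.5).
#' @slot noiseScale Gaussian-noise standard deviation in [0, 1] intensity units
#'   (default 0.08).
#' @slot blurSigma Gaussian-blur sigma in pixels (default 1.0).
#' @slot noiseP,blurP per-image application probabilities for noise and blur
#'   (default 1: always applied).
#' @export
setClass("PreprocessConfig", representation(
  targetSize = "integer", channelMean = "numeric", channelStd = "numeric",
  datasetMean = "numeric", datasetVar = "numeric", flipP = "numeric",
  noiseScale = "numeric", blurSigma = "numeric", noiseP = "numeric",
  blurP = "numeric"
))

setValidity("PreprocessConfig", function(object) {
  msg <- character()
  if (object@targetSize <= 0L) msg <- c(msg, "targetSize must be positive")
  if (any(object@channelStd <= 0)) msg <- c(msg, "channelStd components must be > 0")
  for (p in c(object@flipP, object@noiseP, object@blurP))
    if (p < 0 || p > 1) { msg <- c(msg, "probabilities must be in [0, 1]"); break }
  if (length(msg)) msg else TRUE
})

#' @describeIn PreprocessConfig-class constructor with the default chain
#'   parameters.
#' @param targetSize,channelMean,channelStd,datasetMean,datasetVar,flipP,noiseScale,blurSigma,noiseP,blurP
#'   see slots.
#' @export
PreprocessConfig <- function(targetSize = 1024L,
                             channelMean = c(0.485, 0.456, 0.406),
                             channelStd = c(0.299, 0.224, 0.225),
                             datasetMean = NA_real_, datasetVar = NA_real_,
                             flipP = 0.5, noiseScale = 0.08, blurSigma = 1.0,
                             noiseP = 1, blurP = 1) {
  new("PreprocessConfig", targetSize = as.integer(targetSize),
      channelMean = channelMean, channelStd = channelStd,
      datasetMean = datasetMean, datasetVar = datasetVar, flipP = flipP,
      noiseScale = noiseScale, blurSigma = blurSigma, noiseP = noiseP,
      blurP = blurP)
}

#' SceneConfig: synthetic microscopy scene parameters
#'
#' Defaults emulate phase-contrast frames of human round spermatids: bright
#' ~11 um cells with ~7 um nuclei at 0.212 um/pixel (hence ~52 px cell disks),
#' on a noisy background with unlabelled debris distractors.
#'
#' @slot imageSize frame side in pixels (default 512).
#' @slot pixelSizeUm microns per pixel (default 0.212).
#' @slot cellDiameterUm mean cell diameter in microns (default 11).
#' @slot cellDiameterJitter fractional uniform jitter of the diameter
#'   (default 0.1).
#' @slot nucleusDiameterUm mean nucleus diameter in microns (default 7).
#' @slot cellsPerImage integer range `c(min, max)` of cells per frame.
#' @slot debrisPerImage integer range of debris blobs per frame.
#' @slot backgroundLevel,backgroundNoiseSd,cellIntensity,nucleusIntensity
#'   intensities in [0, 1].
#' @export
setClass("SceneConfig", representation(
  imageSize = "integer", pixelSizeUm = "numeric", cellDiameterUm = "numeric",
  cellDiameterJitter = "numeric", nucleusDiameterUm = "numeric",
  cellsPerImage = "integer", debrisPerImage = "integer",
  backgroundLevel = "numeric", backgroundNoiseSd = "numeric",
  cellIntensity = "numeric", nucleusIntensity = "numeric"
))

setValidity("SceneConfig", function(object) {
  msg <- character()
  if (object@nucleusDiameterUm >= object@cellDiameterUm)
    msg <- c(msg, "nucleus diameter must be smaller than cell diameter")
  ints <- c(object@backgroundLevel, object@cellIntensity, object@nucleusIntensity)
  if (any(ints < 0 | ints > 1)) msg <- c(msg, "intensities must be in [0, 1]")
  if (length(object@cellsPerImage) != 2L || any(object@cellsPerImage < 0L))
    msg <- c(msg, "cellsPerImage must be a non-negative range c(min, max)")
  if (length(msg)) msg else TRUE
})

#' @describeIn SceneConfig-class constructor with round-spermatid-scale
#'   defaults.
#' @param imageSize,pixelSizeUm,cellDiameterUm,cellDiameterJitter,nucleusDiameterUm,cellsPerImage,debrisPerImage,backgroundLevel,backgroundNoiseSd,cellIntensity,nucleusIntensity
#'   see slots.
#' @export
SceneConfig <- function(imageSize = 512L, pixelSizeUm = 0.212,
                        cellDiameterUm = 11, cellDiameterJitter = 0.1,
                        nucleusDiameterUm = 7, cellsPerImage = c(2L, 6L),
                        debrisPerImage = c(2L, 6L), backgroundLevel = 0.15,
                        backgroundNoiseSd = 0.03, cellIntensity = 0.75,
                        nucleusIntensity = 0.55) {
  new("SceneConfig", imageSize = as.integer(imageSize),
      pixelSizeUm = pixelSizeUm, cellDiameterUm = cellDiameterUm,
      cellDiameterJitter = cellDiameterJitter,
      nucleusDiameterUm = nucleusDiameterUm,
      cellsPerImage = as.integer(cellsPerImage),
      debrisPerImage = as.integer(debrisPerImage),
      backgroundLevel = backgroundLevel,
      backgroundNoiseSd = backgroundNoiseSd, cellIntensity = cellIntensity,
      nucleusIntensity = nucleusIntensity)
}

#' ErrorModel: configurable error-injecting mock predictor parameters
#'
#' Drives [mockPredict()]: each ground-truth instance is missed with
#' probability `missRate` or reproduced with a jittered mask and a confidence
#' drawn from `scoreCorrect`; `Poisson(fpRate)` spurious blobs are placed on
#' background with confidences from `scoreSpurious`. Score parameters of
#' length 2 are Beta shape parameters; a single value is a constant score
#' (`scoreCorrect = 1` gives an error-free detector when the rates and jitter
#' are zero).
#'
#' @slot missRate probability a ground-truth instance gets no prediction.
#' @slot fpRate expected spurious predictions per image.
#' @slot jitterPx standard deviation of the integer mask displacement.
#' @slot scoreCorrect,scoreSpurious numeric length 1 (constant) or 2
#'   (Beta shapes).
#' @slot fpRadiusPx nominal radius of spurious blobs in pixels.
#' @export
setClass("ErrorModel", representation(
  missRate = "numeric", fpRate = "numeric", jitterPx = "numeric",
  scoreCorrect = "numeric", scoreSpurious = "numeric", fpRadiusPx = "numeric"
))

setValidity("ErrorModel", function(object) {
  msg <- character()
  if (object@missRate < 0 || object@missRate > 1)
    msg <- c(msg, "missRate must be in [0, 1]")
  if (object@fpRate < 0) msg <- c(msg, "fpRate must be >= 0")
  if (object@jitterPx < 0) msg <- c(msg, "jitterPx must be >= 0")
  for (s in list(object@scoreCorrect, object@scoreSpurious))
    if (!length(s) %in% c(1L, 2L)) { msg <- c(msg, "score params: length 1 or 2"); break }
  if (length(msg)) msg else TRUE
})

#' @describeIn ErrorModel-class constructor; the defaults describe a mildly
#'   error-prone detector.
#' @param missRate,fpRate,jitterPx,scoreCorrect,scoreSpurious,fpRadiusPx see
#'   slots.
#' @export
ErrorModel <- function(missRate = 0.2, fpRate = 1.0, jitterPx = 1.5,
                       scoreCorrect = c(8, 2), scoreSpurious = c(5, 2),
                       fpRadiusPx = 20) {
  new("ErrorModel", missRate = missRate, fpRate = fpRate, jitterPx = jitterPx,
      scoreCorrect = scoreCorrect, scoreSpurious = scoreSpurious,
      fpRadiusPx = fpRadiusPx)
}

#' EvalReport: per-image and aggregate detection-evaluation results
#'
#' @slot bboxMap,maskMap mean average precision in [0, 1] for boxes and masks.
#' @slot perImageBbox,perImageMask per-image terms in [0, 1].
#' @slot nPredictions,nImages,nGt integer counts.
#' @export
setClass("EvalReport", representation(
  bboxMap = "numeric", maskMap = "numeric", perImageBbox = "numeric",
  perImageMask = "numeric", nPredictions = "integer", nImages = "integer",
  nGt = "integer"
))

setValidity("EvalReport", function(object) {
  msg <- character()
  vals <- c(object@bboxMap, object@maskMap, object@perImageBbox, object@perImageMask)
  vals <- vals[!is.na(vals)]
  if (length(vals) && (min(vals) < -1e-12 || max(vals) > 1 + 1e-12))
    msg <- c(msg, "mAP values and per-image terms must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})
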