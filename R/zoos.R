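#' Harvest low-confidence hits on true objects (eq1 zoo candidates)
#'
#' For each prediction whose confidence is strictly below the threshold `c_t`
#' and whose mask intersects the ground-truth foreground, the pixelwise
#' intersection of the prediction with the union of ground-truth masks is
#' tight-cropped and returned as a [RegionCrop-class] (one candidate per
#' qualifying prediction, merging all ground truth it touches). Crops smaller
#' than `minCropSize` on either side are discarded, with the number discarded
#' reported via `message()`. Crop pixels are taken from the raw
#' (pre-normalisation) image so pastes stay photometrically consistent.
#'
#' @param ai the [AnnotatedImage-class] the predictions refer to (supplies the
#'   pixels and ground truth context).
#' @param predictions list of [Prediction-class] with binarised masks.
#' @param config a [ZooConfig-class] (supplies `confidenceThreshold` and
#'   `minCropSize`).
#' @param step training-step counter recorded on the crops.
#' @return list of [RegionCrop-class] with `zooLabel = "eq1_zoo"`.
#' @export
harvestEq1Regions <- function(ai, predictions, config = ZooConfig(), step = 0L) {
  h <- imageHeight(ai); w <- imageWidth(ai)
  gtU <- gtUnionMask(instances(ai), h, w)
  crops <- list(); dropped <- 0L
  for (p in predictions) {
    if (score(p) >= config@confidenceThreshold) next  # strict: score < c_t
    inter <- binMask(p) & gtU
    if (!any(inter)) next
    box <- tightBox(inter)
    if (min(box[3], box[4]) < config@minCropSize) { dropped <- dropped + 1L; next }
    crops[[length(crops) + 1L]] <- RegionCrop(
      pixels = cropToBox(pixels(ai), box), mask = cropToBox(inter, box),
      sourceImageId = imageId(ai), sourceScore = score(p),
      zooLabel = "eq1_zoo", entryStep = step)
  }
  if (dropped > 0L) message(dropped, " sub-minimum eq1 crop(s) discarded")
  crops
}

#' Harvest high-confidence hits on background (eq2 zoo candidates)
#'
#' For each prediction whose confidence is strictly above `c_t` and whose
#' overlap ratio with every ground-truth instance is at most gamma
#' (`overlapThreshold`), the prediction pixels lying outside all ground-truth
#' masks are tight-cropped and returned. The overlap ratio is
#' intersection / prediction-area by default (the fraction of the prediction
#' explained by ground truth), or IoU when `config@overlapMode == "iou"`.
#'
#' @inheritParams harvestEq1Regions
#' @return list of [RegionCrop-class] with `zooLabel = "eq2_zoo"`.
#' @export
harvestEq2Regions <- function(ai, predictions, config = ZooConfig(), step = 0L) {
  h <- imageHeight(ai); w <- imageWidth(ai)
  gtU <- gtUnionMask(instances(ai), h, w)
  crops <- list(); dropped <- 0L
  for (p in predictions) {
    if (score(p) <= config@confidenceThreshold) next  # strict: score > c_t
    pm <- binMask(p)
    pArea <- sum(pm)
    if (pArea == 0L) next
    qualifies <- TRUE
    for (inst in instances(ai)) {
      im <- binMask(inst)
      inter <- sum(pm & im)
      ratio <- if (config@overlapMode == "iou")
        inter / (pArea + sum(im) - inter) else inter / pArea
      if (ratio > config@overlapThreshold) { qualifies <- FALSE; break }
    }
    if (!qualifies) next
    outside <- pm & !gtU
    if (!any(outside)) next
    box <- tightBox(outside)
    if (min(box[3], box[4]) < config@minCropSize) { dropped <- dropped + 1L; next }
    crops[[length(crops) + 1L]] <- RegionCrop(
      pixels = cropToBox(pixels(ai), box), mask = cropToBox(outside, box),
      sourceImageId = imageId(ai), sourceScore = score(p),
      zooLabel = "eq2_zoo", entryStep = step)
  }
  if (dropped > 0L) message(dropped, " sub-minimum eq2 crop(s) discarded")
  crops
}

#' Append crops to a zoo under the bounded-FIFO rule
#'
#' Crops are appended in order; while the zoo exceeds its capacity T, the
#' first-entered (front) element is evicted, so after the update the zoo holds
#' at most T crops -- the most recently added ones.
#'
#' @param zoo a [RegionZoo-class].
#' @param newCrops list of [RegionCrop-class] (may be empty).
#' @return the updated [RegionZoo-class].
#' @export
zooUpdate <- function(zoo, newCrops) {
  entries <- c(zoo@entries, newCrops)
  n <- length(entries)
  if (n > zoo@capacity) entries <- entries[(n - zoo@capacity + 1L):n]
  new("RegionZoo", entries = entries, capacity = zoo@capacity)
}

#' Draw one crop uniformly from a zoo
#'
#' @param zoo a [RegionZoo-class].
#' @param seed optional RNG seed.
#' @return a [RegionCrop-class], or `NULL` for an empty zoo.
#' @export
zooSample <- function(zoo, seed = NULL) {
  n <- length(zoo@entries)
  if (n == 0L) return(NULL)
  zoo@entries[[withSeed(seed, sample.int(n, 1L))]]
}

#' Paper-name aliases for the two zoos
#'
#' The update rule collecting low-confidence detector hits on true objects is
#' published under the name "FP Zoo" and the rule collecting high-confidence
#' hits on background under "FN Zoo"; internally this package labels them by
#' their defining rule (`eq1_zoo`, `eq2_zoo`) because the published names
#' invert the classical false-positive/false-negative reading. These helpers
#' expose the published naming.
#'
#' @param eq1Zoo,eq2Zoo [RegionZoo-class] objects as returned by
#'   [runDemoLoop()] or maintained manually.
#' @return the corresponding zoo.
#' @export
fpZoo <- function(eq1Zoo) eq1Zoo

#' @rdname fpZoo
#' @export
fnZoo <- function(eq2Zoo) eq2Zoo

#' Checkpoint and restore zoo state
#'
#' `zooSave()`/`zooLoad()` round-trip a zoo bit-exactly through an RDS file.
#'
#' @param zoo a [RegionZoo-class] object.
#' @param path checkpoint file.
#' @return `zooLoad` returns the restored [RegionZoo-class]; `zooSave` its
#'   `path`, invisibly.
#' @export
zooSave <- function(zoo, path) {
  stopifnot(is(zoo, "RegionZoo"))
  saveRDS(zoo, path)
  invisible(path)
}

#' @rdname zooSave
#' @export
zooLoad <- function(path) {
  zoo <- readRDS(path)
  if (!is(zoo, "RegionZoo")) stop("not a RegionZoo checkpoint: ", path)
  validObject(zoo)
  zoo
}

#' Serialise zoo contents for audit
#'
#' Writes each crop's pixel patch and mask as PNG files plus a JSON metadata
#' table (source image, score, entry step, zoo label) into `outDir`.
#'
#' @param zoos named list of [RegionZoo-class] objects.
#' @param outDir output directory.
#' @return invisibly, the metadata JSON path.
#' @export
inspectZoos <- function(zoos, outDir) {
  if (!dir.exists(outDir) && !dir.create(outDir, recursive = TRUE))
    stop("cannot create ", outDir)
  meta <- list()
  for (zname in names(zoos)) {
    entries <- zooEntries(zoos[[zname]])
    for (i in seq_along(entries)) {
      e <- entries[[i]]
      base <- sprintf("%s_%03d", zname, i)
      EBImage::writeImage(toEBImage(clip01(e@pixels)),
                          file.path(outDir, paste0(base, "_pixels.png")))
      EBImage::writeImage(toEBImage(e@mask * 1),
                          file.path(outDir, paste0(base, "_mask.png")))
      meta[[length(meta) + 1L]] <- list(
        zoo = zname, index = i, file = base, zooLabel = e@zooLabel,
        sourceImageId = e@sourceImageId, sourceScore = e@sourceScore,
        entryStep = e@entryStep,
        height = nrow(e@mask), width = ncol(e@mask))
    }
  }
  path <- file.path(outDir, "zoo_metadata.json")
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}
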