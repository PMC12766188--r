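## Synthetic microscopy scenes: bright round cells (~52 px at the default
## 0.212 um/px optics) with dimmer nuclei on a noisy background, plus
## unlabelled debris distractors. Sufficient for geometry/label correctness;
## not a phase-contrast optics simulation.

diskMask <- function(h, w, cx, cy, r) {
  ys <- matrix(seq_len(h) - 0.5, h, w)
  xs <- matrix(rep(seq_len(w) - 0.5, each = h), h, w)
  (xs - cx)^2 + (ys - cy)^2 <= r^2
}

## Star-shaped irregular polygon mask around (cx, cy) with radii in
## [rMin, rMax]; used for debris.
blobMask <- function(h, w, cx, cy, rMin, rMax, nVert = 8L) {
  ang <- sort(stats::runif(nVert, 0, 2 * pi))
  rad <- stats::runif(nVert, rMin, rMax)
  xy <- as.vector(rbind(cx + rad * cos(ang), cy + rad * sin(ang)))
  polygonToMask(xy, h, w)
}

#' Generate one synthetic annotated microscopy scene
#'
#' Draws a noisy background, places non-overlapping bright cell disks (each a
#' ground-truth instance whose mask is the cell disk, containing a dimmer
#' nucleus disk) and scatters irregular lower-intensity debris blobs that
#' receive no annotation. Cell diameters are sampled around
#' `cellDiameterUm / pixelSizeUm` pixels (about 52 px at the defaults).
#'
#' @param config a [SceneConfig-class].
#' @param seed optional RNG seed (same seed, same scene).
#' @param imageId integer id for the generated image.
#' @return an [AnnotatedImage-class] with grayscale pixels in [0, 1].
#' @export
generateImage <- function(config = SceneConfig(), seed = NULL, imageId = 1L) {
  if (!is.null(seed)) set.seed(seed)
  side <- config@imageSize
  px <- matrix(stats::rnorm(side * side, config@backgroundLevel,
                            config@backgroundNoiseSd), side, side)

  nCells <- if (config@cellsPerImage[1] == config@cellsPerImage[2])
    config@cellsPerImage[1]
  else sample(config@cellsPerImage[1]:config@cellsPerImage[2], 1L)
  rNominal <- config@cellDiameterUm / config@pixelSizeUm / 2

  centers <- matrix(numeric(0), ncol = 3)  # cx, cy, r
  insts <- list()
  for (i in seq_len(nCells)) {
    r <- rNominal * (1 + stats::runif(1, -config@cellDiameterJitter,
                                      config@cellDiameterJitter))
    placed <- FALSE
    for (attempt in 1:200) {
      cx <- stats::runif(1, r + 1, side - r - 1)
      cy <- stats::runif(1, r + 1, side - r - 1)
      if (nrow(centers) == 0L ||
          all(sqrt((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2) >
              centers[, 3] + r + 2)) { placed <- TRUE; break }
    }
    if (!placed)
      stop("infeasible packing: could not place cell ", i, " of ", nCells,
           " after 200 attempts in a ", side, " px frame")
    centers <- rbind(centers, c(cx, cy, r))
    cell <- diskMask(side, side, cx, cy, r)
    rN <- r * config@nucleusDiameterUm / config@cellDiameterUm
    off <- stats::runif(2, -0.15 * r, 0.15 * r)
    nucleus <- diskMask(side, side, cx + off[1], cy + off[2], rN)
    jitterI <- stats::runif(1, -0.04, 0.04)
    px[cell] <- config@cellIntensity + jitterI
    px[nucleus & cell] <- config@nucleusIntensity + jitterI
    insts[[i]] <- Instance(cell, instanceId = i)
  }

  nDebris <- if (config@debrisPerImage[1] == config@debrisPerImage[2])
    config@debrisPerImage[1]
  else sample(config@debrisPerImage[1]:config@debrisPerImage[2], 1L)
  cellU <- gtUnionMask(insts, side, side)
  for (d in seq_len(nDebris)) {
    for (attempt in 1:50) {
      cx <- stats::runif(1, 12, side - 12); cy <- stats::runif(1, 12, side - 12)
      bm <- blobMask(side, side, cx, cy, 4, 12)
      if (!any(bm & cellU)) {
        px[bm] <- config@backgroundLevel + stats::runif(1, 0.12, 0.3)
        break
      }
    }
  }
  AnnotatedImage(clip01(px), imageId = imageId, instances = insts)
}

#' Generate a synthetic COCO dataset on disk
#'
#' Writes `nImages` scenes as PNG files plus one COCO annotation JSON,
#' readable by [readCocoDataset()] with zero warnings (masks round-trip
#' pixel-exactly through RLE).
#'
#' @param nImages number of images (>= 1).
#' @param config a [SceneConfig-class].
#' @param outDir output directory.
#' @param seed RNG seed.
#' @return invisibly, the annotation JSON path.
#' @export
generateDataset <- function(nImages, config = SceneConfig(), outDir,
                            seed = 1L) {
  stopifnot(nImages >= 1)
  set.seed(seed)
  seeds <- childSeeds(nImages)
  dataset <- lapply(seq_len(nImages), function(i)
    generateImage(config, seed = seeds[i], imageId = i))
  writeCocoDataset(dataset, outDir)
}

#' In-memory list of synthetic scenes
#'
#' Convenience wrapper: `nImages` scenes with ids `1:nImages`, reproducible
#' from `seed`.
#'
#' @inheritParams generateDataset
#' @return list of [AnnotatedImage-class].
#' @export
generateScenes <- function(nImages, config = SceneConfig(), seed = 1L) {
  set.seed(seed)
  seeds <- childSeeds(nImages)
  lapply(seq_len(nImages), function(i)
    generateImage(config, seed = seeds[i], imageId = i))
}

## Shift a mask by integer (dx, dy), dropping pixels that leave the frame.
shiftMask <- function(mask, dx, dy) {
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(FALSE, h, w)
  srcR <- intersect(seq_len(h), seq_len(h) - dy)
  srcC <- intersect(seq_len(w), seq_len(w) - dx)
  if (length(srcR) && length(srcC))
    out[srcR + dy, srcC + dx] <- mask[srcR, srcC]
  out
}

drawScore <- function(param) {
  if (length(param) == 1L) param else stats::rbeta(1, param[1], param[2])
}

#' Error-injecting mock predictor
#'
#' Stand-in for a trained detector: each ground-truth instance is either
#' missed (probability `missRate`) or reproduced with an integer-jittered mask
#' and a confidence drawn from `scoreCorrect`; `Poisson(fpRate)` spurious disk
#' predictions are placed with their centre on background with confidences
#' from `scoreSpurious`. With zero rates, zero jitter and `scoreCorrect = 1`
#' the predictions equal the ground truth exactly.
#'
#' @param ai an [AnnotatedImage-class].
#' @param model an [ErrorModel-class].
#' @param seed optional RNG seed.
#' @return list of [Prediction-class] carrying `imageId(ai)`.
#' @export
mockPredict <- function(ai, model = ErrorModel(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  h <- imageHeight(ai); w <- imageWidth(ai)
  preds <- list()
  for (inst in instances(ai)) {
    if (stats::runif(1) < model@missRate) next
    m <- binMask(inst)
    if (model@jitterPx > 0) {
      sh <- round(stats::rnorm(2, 0, model@jitterPx))
      m <- shiftMask(m, sh[1], sh[2])
      if (!any(m)) next
    }
    preds[[length(preds) + 1L]] <- Prediction(
      m, score = drawScore(model@scoreCorrect), imageId = imageId(ai))
  }
  nFp <- stats::rpois(1, model@fpRate)
  if (nFp > 0) {
    gtU <- gtUnionMask(instances(ai), h, w)
    for (f in seq_len(nFp)) {
      for (attempt in 1:50) {
        r <- model@fpRadiusPx * stats::runif(1, 0.5, 1.1)
        cx <- stats::runif(1, r + 1, w - r - 1)
        cy <- stats::runif(1, r + 1, h - r - 1)
        if (!gtU[ceiling(cy), ceiling(cx)]) {
          preds[[length(preds) + 1L]] <- Prediction(
            diskMask(h, w, cx, cy, r), score = drawScore(model@scoreSpurious),
            imageId = imageId(ai))
          break
        }
      }
    }
  }
  preds
}

#' Mock predictor whose error rates shrink with exposure to pasted hard
#' examples
#'
#' A closure around an [ErrorModel-class]: its effective miss rate decays
#' exponentially with the number of labelled (eq1) pastes it has been exposed
#' to, and its spurious-detection rate with the number of unlabelled (eq2)
#' pastes, `rate * exp(-learnRate * exposures)`. [runDemoLoop()] feeds it the
#' paste log of each augmented image, so runs with confusion duplicate
#' disabled leave the rates at their base values. Used for qualitative
#' directional comparisons of augmented vs unaugmented training.
#'
#' @param model base [ErrorModel-class].
#' @param learnRate exponential decay per exposure (default 0.04).
#' @return an object of class `adaptiveMockPredictor`: a list with `predict`
#'   (`function(ai)`), `notePastes` (`function(pasteLog)`) and `state`
#'   (`function()` returning the exposure counters and effective rates).
#' @export
adaptiveMockPredictor <- function(model = ErrorModel(), learnRate = 0.04) {
  env <- new.env(parent = emptyenv())
  env$eq1Seen <- 0L; env$eq2Seen <- 0L
  effective <- function() {
    m <- model
    m@missRate <- model@missRate * exp(-learnRate * env$eq1Seen)
    m@fpRate <- model@fpRate * exp(-learnRate * env$eq2Seen)
    m
  }
  structure(list(
    predict = function(ai) mockPredict(ai, effective()),
    notePastes = function(pasteLog) {
      acc <- pasteLog[pasteLog$accepted, , drop = FALSE]
      env$eq1Seen <- env$eq1Seen + sum(acc$zoo == "eq1_zoo")
      env$eq2Seen <- env$eq2Seen + sum(acc$zoo == "eq2_zoo")
      invisible(NULL)
    },
    state = function() list(eq1Seen = env$eq1Seen, eq2Seen = env$eq2Seen,
                            missRate = effective()@missRate,
                            fpRate = effective()@fpRate)
  ), class = "adaptiveMockPredictor")
}

## Validate the adapter contract: a predictor must return a list of Prediction
## objects with frame-sized masks and scores in [0, 1].
checkPredictionContract <- function(preds, ai) {
  if (!is.list(preds))
    stop("prediction contract violated: predictor must return a list, got ",
         class(preds)[1])
  d <- dim(pixels(ai))[1:2]
  for (p in preds) {
    if (!is(p, "Prediction"))
      stop("prediction contract violated: element of class ", class(p)[1],
           " is not a Prediction")
    if (!identical(dim(binMask(p)), d))
      stop("prediction contract violated: mask dimensions ",
           paste(dim(binMask(p)), collapse = "x"), " do not match image ",
           paste(d, collapse = "x"))
    if (score(p) < 0 || score(p) > 1)
      stop("prediction contract violated: score ", score(p), " outside [0, 1]")
  }
  invisible(TRUE)
}

#' Desk-scale training-loop demo with detector feedback
#'
#' Iterates over training images applying the per-iteration hook sequence:
#' sample/paste (confusion duplicate) then regional drop before the step, a
#' detector forward pass (mock predictor or any adapter-contract function),
#' then zoo updates from that iteration's output. Returns the final zoos, an
#' evaluation on a held-out split, and per-iteration logs.
#'
#' @param dataset non-empty list of [AnnotatedImage-class]; the last
#'   `ceiling(evalFraction * n)` images (after a seeded shuffle) are held out
#'   for evaluation unless `evalDataset` is given.
#' @param predictor an [ErrorModel-class] (drives [mockPredict()]), an
#'   [adaptiveMockPredictor()], or a `function(ai)` returning a list of
#'   [Prediction-class] (violations of that contract are hard errors naming
#'   the violation).
#' @param zooConfig a [ZooConfig-class].
#' @param augmentConfig an [AugmentConfig-class]; `p1 = 0` disables pasting,
#'   `p2 = 0` disables regional drop.
#' @param nIters number of training iterations (batch size 1; images are
#'   cycled).
#' @param seed integer seed; fixed seed gives bit-identical logs.
#' @param evalDataset optional explicit held-out list of
#'   [AnnotatedImage-class].
#' @param evalFraction held-out fraction when `evalDataset` is NULL.
#' @return list with `eq1Zoo`, `eq2Zoo`, `report` (an [EvalReport-class]
#'   computed on the held-out split with the predictor's final state), and
#'   `logs` (data.frame: iteration, imageId, zoo sizes, paste/drop/prediction
#'   counts).
#' @export
runDemoLoop <- function(dataset, predictor, zooConfig = ZooConfig(),
                        augmentConfig = AugmentConfig(),
                        nIters = length(dataset), seed = 1L,
                        evalDataset = NULL, evalFraction = 0.1) {
  stopifnot(length(dataset) > 0L)
  set.seed(seed)

  adaptive <- inherits(predictor, "adaptiveMockPredictor")
  predictFun <- if (adaptive) predictor$predict
    else if (is(predictor, "ErrorModel")) function(ai) mockPredict(ai, predictor)
    else if (is.function(predictor)) predictor
    else stop("predictor must be an ErrorModel, an adaptiveMockPredictor or a function")

  if (is.null(evalDataset)) {
    nEval <- max(1L, ceiling(evalFraction * length(dataset)))
    if (nEval >= length(dataset))
      stop("dataset too small to hold out ", nEval, " image(s)")
    ord <- sample.int(length(dataset))
    evalDataset <- dataset[ord[seq_len(nEval)]]
    trainSet <- dataset[ord[-seq_len(nEval)]]
  } else trainSet <- dataset

  eq1Zoo <- RegionZoo(capacity = zooConfig@capacity)
  eq2Zoo <- RegionZoo(capacity = zooConfig@capacity)
  logs <- data.frame(iteration = integer(nIters), imageId = integer(nIters),
                     eq1Size = integer(nIters), eq2Size = integer(nIters),
                     pastesEq1 = integer(nIters), pastesEq2 = integer(nIters),
                     dropRegions = integer(nIters),
                     nPredictions = integer(nIters),
                     nInstances = integer(nIters))

  for (it in seq_len(nIters)) {
    ai <- trainSet[[((it - 1L) %% length(trainSet)) + 1L]]
    # before-step hooks: paste then drop (pasted regions are drop-eligible)
    cd <- confusionDuplicate(ai, eq1Zoo, eq2Zoo, augmentConfig)
    regions <- dropRegions(cd$image, cd$pasteLog)
    aug <- regionalDrop(cd$image, regions, augmentConfig)
    if (adaptive) predictor$notePastes(cd$pasteLog)
    # forward pass
    preds <- predictFun(aug)
    checkPredictionContract(preds, aug)
    # after-step hooks: zoo updates from this iteration's output
    eq1Zoo <- zooUpdate(eq1Zoo, suppressMessages(
      harvestEq1Regions(aug, preds, zooConfig, step = it)))
    eq2Zoo <- zooUpdate(eq2Zoo, suppressMessages(
      harvestEq2Regions(aug, preds, zooConfig, step = it)))
    acc <- cd$pasteLog[cd$pasteLog$accepted, , drop = FALSE]
    logs[it, ] <- list(it, imageId(ai), zooSize(eq1Zoo), zooSize(eq2Zoo),
                       sum(acc$zoo == "eq1_zoo"), sum(acc$zoo == "eq2_zoo"),
                       length(regions), length(preds),
                       length(instances(aug)))
  }

  evalPreds <- do.call(c, lapply(evalDataset, predictFun))
  if (is.null(evalPreds)) evalPreds <- list()
  report <- evaluateDataset(evalPreds, evalDataset, mode = "both")
  list(eq1Zoo = eq1Zoo, eq2Zoo = eq2Zoo, report = report, logs = logs)
}
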