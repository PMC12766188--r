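#' Union-overlap ratio (IoU) between two boxes or masks
#'
#' Intersection area over union area; a prediction and a ground-truth object
#' are considered a match when this ratio is strictly greater than 0.5. A
#' zero-area union yields 0.
#'
#' @param a,b boxes (`mode = "bbox"`, numeric(4) `[x, y, w, h]`) or full-frame
#'   logical masks (`mode = "mask"`).
#' @param mode `"bbox"` or `"mask"`.
#' @return the ratio in [0, 1].
#' @export
overlapUnionRatio <- function(a, b, mode = c("bbox", "mask")) {
  mode <- match.arg(mode)
  if (mode == "bbox") boxIoU(a, b) else maskIoU(asMask(a), asMask(b))
}

#' Greedy score-ordered matching of predictions to ground truth
#'
#' Predictions are processed in descending score order (ties broken by
#' ascending input index, i.e. stable); each is correct iff its union-overlap
#' ratio with some not-yet-matched ground-truth instance exceeds 0.5 (strict).
#' Each ground-truth instance can be matched by at most one prediction.
#'
#' @param predictions list of [Prediction-class].
#' @param gtInstances list of [Instance-class].
#' @param mode `"bbox"` or `"mask"`.
#' @return data.frame in processing (descending-score) order with columns
#'   `predIndex` (original position), `score`, `correct`, `matchedGt`
#'   (instance id or NA) and `overlap` (ratio with the matched instance, or
#'   the best ratio among unmatched instances when incorrect).
#' @export
matchImage <- function(predictions, gtInstances, mode = c("bbox", "mask")) {
  mode <- match.arg(mode)
  n <- length(predictions)
  scores <- vapply(predictions, score, numeric(1))
  ord <- order(-scores, seq_len(n))
  matched <- rep(FALSE, length(gtInstances))
  out <- data.frame(predIndex = integer(n), score = numeric(n),
                    correct = logical(n), matchedGt = integer(n),
                    overlap = numeric(n))
  for (r in seq_len(n)) {
    i <- ord[r]
    p <- predictions[[i]]
    best <- 0; bestG <- NA_integer_
    for (g in seq_along(gtInstances)) {
      if (matched[g]) next
      ratio <- if (mode == "bbox") boxIoU(bbox(p), bbox(gtInstances[[g]]))
               else maskIoU(binMask(p), binMask(gtInstances[[g]]))
      if (ratio > best) { best <- ratio; bestG <- g }
    }
    correct <- best > 0.5
    if (correct) matched[bestG] <- TRUE
    out[r, ] <- list(i, scores[i],
                     correct,
                     if (correct) instanceId(gtInstances[[bestG]]) else NA_integer_,
                     best)
  }
  out
}

#' Per-image precision-weighted mean average precision
#'
#' For image i with score-sorted predictions, the per-image term is
#' `sum_c Pr(s_i^c) * I(s_i^c) / sum_t I(s_i^t)`, where `Pr(s_i^c)` is the
#' precision over the first c predictions and `I` indicates a correct
#' prediction under the strict >0.5 union-overlap match rule; an image whose
#' correct-prediction count is zero contributes 0. The score is the mean term
#' over all N evaluated images (including images with no ground truth and no
#' predictions).
#'
#' Note the normaliser is the number of *correct* predictions, not the
#' ground-truth count: this metric is precision-flavoured and differs from the
#' COCO average precision, which [cocoAveragePrecision()] provides as a
#' clearly-named alternative.
#'
#' @param predictions list of [Prediction-class]; each must reference an image
#'   present in `dataset` (unknown `imageId` is a hard error).
#' @param dataset list of [AnnotatedImage-class] defining the N evaluated
#'   images.
#' @param mode `"bbox"` or `"mask"`.
#' @return the score in [0, 1].
#' @export
mapScore <- function(predictions, dataset, mode = c("bbox", "mask")) {
  mode <- match.arg(mode)
  mean(mapPerImageTerms(predictions, dataset, mode))
}

## Per-image terms of the metric (shared by mapScore and evaluateDataset).
mapPerImageTerms <- function(predictions, dataset, mode) {
  ids <- vapply(dataset, imageId, integer(1))
  pids <- vapply(predictions, imageId, integer(1))
  unknown <- setdiff(pids, ids)
  if (length(unknown))
    stop("prediction references unknown image id(s): ",
         paste(unknown, collapse = ", "))
  vapply(seq_along(dataset), function(k) {
    preds <- predictions[pids == ids[k]]
    if (length(preds) == 0L) return(0)
    mr <- matchImage(preds, instances(dataset[[k]]), mode)
    nCorrect <- sum(mr$correct)
    if (nCorrect == 0L) return(0)
    prec <- cumsum(mr$correct) / seq_len(nrow(mr))
    sum(prec * mr$correct) / nCorrect
  }, numeric(1))
}

#' Literal brute-force reference of the mAP metric
#'
#' Unoptimised independent re-evaluation used as an oracle in tests: for every
#' image and every cutoff c the precision over the first c predictions is
#' recounted from scratch with its own matching and rectangle/mask overlap
#' code, sharing nothing with [mapScore()].
#'
#' @inheritParams mapScore
#' @return the score in [0, 1].
#' @export
mapScoreBruteforce <- function(predictions, dataset, mode = c("bbox", "mask")) {
  mode <- match.arg(mode)
  ratio <- function(p, g) {
    if (mode == "bbox") {
      a <- bbox(p); b <- bbox(g)
      x1 <- max(a[1], b[1]); y1 <- max(a[2], b[2])
      x2 <- min(a[1] + a[3], b[1] + b[3]); y2 <- min(a[2] + a[4], b[2] + b[4])
      inter <- max(0, x2 - x1) * max(0, y2 - y1)
      un <- a[3] * a[4] + b[3] * b[4] - inter
      if (un <= 0) 0 else inter / un
    } else {
      am <- binMask(p); bm <- binMask(g)
      inter <- 0; un <- 0
      for (idx in seq_along(am)) {
        if (am[idx] && bm[idx]) inter <- inter + 1
        if (am[idx] || bm[idx]) un <- un + 1
      }
      if (un == 0) 0 else inter / un
    }
  }
  for (p in predictions)
    if (!any(vapply(dataset, function(d) imageId(d) == imageId(p), logical(1))))
      stop("prediction references unknown image id ", imageId(p))
  terms <- numeric(length(dataset))
  for (k in seq_along(dataset)) {
    ai <- dataset[[k]]
    preds <- Filter(function(p) imageId(p) == imageId(ai), predictions)
    if (length(preds) == 0L) { terms[k] <- 0; next }
    sc <- vapply(preds, score, numeric(1))
    preds <- preds[order(-sc, seq_along(sc))]
    gts <- instances(ai)
    taken <- rep(FALSE, length(gts))
    correct <- logical(length(preds))
    for (c_ in seq_along(preds)) {
      best <- 0; bestG <- 0
      for (g in seq_along(gts)) {
        if (taken[g]) next
        r <- ratio(preds[[c_]], gts[[g]])
        if (r > best) { best <- r; bestG <- g }
      }
      if (best > 0.5) { correct[c_] <- TRUE; taken[bestG] <- TRUE }
    }
    num <- 0
    for (c_ in seq_along(preds)) {
      if (!correct[c_]) next
      nCorrectSoFar <- 0
      for (j in 1:c_) if (correct[j]) nCorrectSoFar <- nCorrectSoFar + 1
      num <- num + nCorrectSoFar / c_
    }
    den <- sum(correct)
    terms[k] <- if (den == 0) 0 else num / den
  }
  if (length(terms) == 0L) return(0)
  sum(terms) / length(terms)
}

#' COCO-style average precision at IoU 0.5 (alternative metric)
#'
#' Standard detection AP: predictions are pooled across images, sorted by
#' score, matched greedily at the strict >0.5 union-overlap rule, and the
#' precision-recall curve is integrated (all-point interpolation) with recall
#' normalised by the ground-truth count. Provided for comparison only; the
#' package's default metric is [mapScore()].
#'
#' @inheritParams mapScore
#' @return AP in [0, 1].
#' @export
cocoAveragePrecision <- function(predictions, dataset, mode = c("bbox", "mask")) {
  mode <- match.arg(mode)
  ids <- vapply(dataset, imageId, integer(1))
  nGt <- sum(vapply(dataset, function(d) length(instances(d)), integer(1)))
  if (nGt == 0L || length(predictions) == 0L) return(0)
  correct <- logical(0)
  scores <- numeric(0)
  for (k in seq_along(dataset)) {
    preds <- Filter(function(p) imageId(p) == ids[k], predictions)
    if (!length(preds)) next
    mr <- matchImage(preds, instances(dataset[[k]]), mode)
    correct <- c(correct, mr$correct)
    scores <- c(scores, mr$score)
  }
  ord <- order(-scores)
  correct <- correct[ord]
  tp <- cumsum(correct)
  prec <- tp / seq_along(correct)
  rec <- tp / nGt
  # all-point interpolation: running max of precision from the right
  precI <- rev(cummax(rev(prec)))
  sum(diff(c(0, rec)) * precI)
}

#' Evaluate predictions against a dataset
#'
#' Computes the per-image precision-weighted mAP ([mapScore()]) for boxes and
#' masks and assembles an [EvalReport-class].
#'
#' @inheritParams mapScore
#' @param mode `"both"` (default), `"bbox"` or `"mask"`; the omitted mode is
#'   reported as `NA`.
#' @return an [EvalReport-class].
#' @export
evaluateDataset <- function(predictions, dataset, mode = c("both", "bbox", "mask")) {
  mode <- match.arg(mode)
  nGt <- sum(vapply(dataset, function(d) length(instances(d)), integer(1)))
  tb <- if (mode %in% c("both", "bbox"))
    mapPerImageTerms(predictions, dataset, "bbox") else NA_real_
  tm <- if (mode %in% c("both", "mask"))
    mapPerImageTerms(predictions, dataset, "mask") else NA_real_
  new("EvalReport",
      bboxMap = if (all(is.na(tb))) NA_real_ else mean(tb),
      maskMap = if (all(is.na(tm))) NA_real_ else mean(tm),
      perImageBbox = tb, perImageMask = tm,
      nPredictions = length(predictions), nImages = length(dataset),
      nGt = as.integer(nGt))
}

#' Write an EvalReport as JSON
#'
#' @param report an [EvalReport-class].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
writeEvalReport <- function(report, path) {
  jsonlite::write_json(list(
    bbox_map = report@bboxMap, mask_map = report@maskMap,
    per_image_bbox = report@perImageBbox, per_image_mask = report@perImageMask,
    n_predictions = report@nPredictions, n_images = report@nImages,
    n_gt = report@nGt), path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}
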