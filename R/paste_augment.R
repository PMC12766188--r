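#' Confusion duplicate: paste sampled zoo crops into an image
#'
#' Independently for each zoo, with probability `p1`, `pastesPerZoo` crops are
#' drawn uniformly and pasted: crop pixels are copied through the crop mask at
#' a uniformly chosen location whose pasted footprint has IoU at most
#' `maxPasteOverlap` with every existing instance (rejection sampling, up to
#' `maxPlaceAttempts`; on failure the paste is skipped and logged).
#'
#' Label semantics: crops from the eq1 zoo are pixel subsets of true objects
#' and are added to the ground truth as new instances; crops from the eq2 zoo
#' are confusing background and are pasted without any annotation.
#'
#' @param ai an [AnnotatedImage-class] in raw (pre-normalisation) intensity
#'   space.
#' @param eq1Zoo,eq2Zoo [RegionZoo-class] objects.
#' @param config an [AugmentConfig-class].
#' @param seed optional RNG seed.
#' @return list with `image` (augmented [AnnotatedImage-class]) and
#'   `pasteLog`, a data.frame with one row per attempted paste: `zoo`,
#'   `accepted`, `x`, `y`, `w`, `h`, `labeled`, `reason`.
#' @export
confusionDuplicate <- function(ai, eq1Zoo, eq2Zoo, config = AugmentConfig(),
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  h <- imageHeight(ai); w <- imageWidth(ai)
  log <- data.frame(zoo = character(), accepted = logical(), x = numeric(),
                    y = numeric(), w = numeric(), h = numeric(),
                    labeled = logical(), reason = character())
  if (config@p1 <= 0) return(list(image = ai, pasteLog = log))

  addRow <- function(zoo, accepted, x = NA, y = NA, cw = NA, ch = NA,
                     labeled = FALSE, reason = "") {
    log[nrow(log) + 1L, ] <<- list(zoo, accepted, x, y, cw, ch, labeled, reason)
  }

  for (zname in c("eq1_zoo", "eq2_zoo")) {
    zoo <- if (zname == "eq1_zoo") eq1Zoo else eq2Zoo
    if (stats::runif(1) >= config@p1) next
    if (zooSize(zoo) == 0L) next
    for (j in seq_len(config@pastesPerZoo)) {
      crop <- zooSample(zoo)
      cm <- binMask(crop)
      ch <- nrow(cm); cw <- ncol(cm)
      if (ch > h || cw > w) {
        warning("zoo crop (", cw, " x ", ch, ") larger than image; skipped")
        addRow(zname, FALSE, reason = "crop_larger_than_image")
        next
      }
      placed <- FALSE
      for (attempt in seq_len(config@maxPlaceAttempts)) {
        x0 <- sample.int(w - cw + 1L, 1L) - 1L
        y0 <- sample.int(h - ch + 1L, 1L) - 1L
        fp <- embedMask(cm, h, w, x0, y0)
        ok <- TRUE
        for (inst in instances(ai)) {
          if (maskIoU(fp, binMask(inst)) > config@maxPasteOverlap) { ok <- FALSE; break }
        }
        if (!ok) next
        ai <- pasteCrop(ai, crop, x0, y0, labeled = zname == "eq1_zoo",
                        feather = config@featherEdges)
        addRow(zname, TRUE, x0, y0, cw, ch, labeled = zname == "eq1_zoo")
        placed <- TRUE
        break
      }
      if (!placed && !(ch > h || cw > w))
        addRow(zname, FALSE, reason = "no_valid_placement")
    }
  }
  list(image = ai, pasteLog = log)
}

## Copy crop pixels through its mask at 0-based (x0, y0); optionally add the
## footprint as a new ground-truth instance.
pasteCrop <- function(ai, crop, x0, y0, labeled, feather = FALSE) {
  px <- pixels(ai)
  cm <- binMask(crop)
  cpx <- crop@pixels
  rows <- (y0 + 1):(y0 + nrow(cm)); cols <- (x0 + 1):(x0 + ncol(cm))
  nc <- nChannels(px)
  ncc <- nChannels(cpx)
  weight <- if (feather) featherWeight(cm) else cm * 1
  for (k in seq_len(nc)) {
    tgt <- if (nc == 1L) px[rows, cols] else px[rows, cols, k]
    src <- if (ncc == 1L) {
      if (length(dim(cpx)) == 3L) cpx[, , 1L] else cpx
    } else cpx[, , min(k, ncc)]
    blended <- tgt * (1 - weight) + src * weight
    if (nc == 1L) px[rows, cols] <- blended else px[rows, cols, k] <- blended
  }
  ai@pixels <- px
  if (labeled) {
    full <- embedMask(cm, imageHeight(ai), imageWidth(ai), x0, y0)
    ids <- vapply(instances(ai), instanceId, integer(1))
    newId <- if (length(ids)) max(ids) + 1L else 1L
    ai@instances <- c(ai@instances, Instance(full, instanceId = newId))
  }
  ai
}

## 1-px Gaussian edge feather: interior weight 1, ramping to ~0.6 on the mask
## boundary.
featherWeight <- function(cm) {
  wgt <- gaussianBlur(cm * 1, sigma = 1)
  wgt[!cm] <- 0
  wgt / max(wgt)
}

#' Regional drop: zero k x k blocks inside informative regions
#'
#' Independently for each region, with probability `p2`, `blocksPerRegion`
#' blocks of side `k` at uniform positions fully inside the region's bounding
#' box are set to 0 in all channels. The drop is photometric only: annotations
#' are never changed. If `k` exceeds a region side, the block is clamped to
#' the region extent (a region smaller than `k` is zeroed entirely).
#'
#' @param ai an [AnnotatedImage-class] in raw intensity space.
#' @param regions list of 0-based `[x, y, w, h]` boxes: the current
#'   ground-truth instance boxes plus this image's pasted footprints (see
#'   [dropRegions()]).
#' @param config an [AugmentConfig-class] (`p2`, `dropBlockK`,
#'   `blocksPerRegion`).
#' @param seed optional RNG seed.
#' @return the [AnnotatedImage-class] with blocks zeroed.
#' @export
regionalDrop <- function(ai, regions, config = AugmentConfig(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (config@p2 <= 0 || length(regions) == 0L) return(ai)
  px <- pixels(ai)
  for (box in regions) {
    if (stats::runif(1) >= config@p2) next
    box <- round(box)  # boxes may carry sub-pixel coords after resizing
    k <- resolveBlockSize(box, config)
    bw <- min(k, box[3]); bh <- min(k, box[4])
    if (bw < k || bh < k)
      message("drop block clamped to region extent (", box[3], " x ", box[4], ")")
    for (b in seq_len(config@blocksPerRegion)) {
      x0 <- box[1] + sample.int(box[3] - bw + 1L, 1L) - 1L
      y0 <- box[2] + sample.int(box[4] - bh + 1L, 1L) - 1L
      rows <- (y0 + 1):(y0 + bh); cols <- (x0 + 1):(x0 + bw)
      if (length(dim(px)) == 3L) px[rows, cols, ] <- 0 else px[rows, cols] <- 0
    }
  }
  ai@pixels <- px
  ai
}

#' Resolve the drop-block side for a region
#'
#' A numeric `dropBlockK` is used as-is; the automatic setting (`NA`) scales
#' the block to a quarter of the region's short side,
#' `max(1, floor(min(w, h) / 4))`.
#'
#' @param regionBox numeric(4) `[x, y, w, h]` with positive extent.
#' @param config an [AugmentConfig-class].
#' @return integer block side k.
#' @export
resolveBlockSize <- function(regionBox, config = AugmentConfig()) {
  stopifnot(regionBox[3] > 0, regionBox[4] > 0)
  if (!is.na(config@dropBlockK)) return(as.integer(config@dropBlockK))
  max(1L, floor(min(regionBox[3], regionBox[4]) / 4))
}

#' Informative regions eligible for regional drop
#'
#' The union of the current ground-truth instance boxes and the accepted
#' pasted footprints from a [confusionDuplicate()] log (both labelled and
#' unlabelled pastes). Ground-truth boxes already include labelled pastes, so
#' those are not duplicated.
#'
#' @param ai the augmented [AnnotatedImage-class].
#' @param pasteLog data.frame from [confusionDuplicate()] (optional).
#' @return list of numeric(4) boxes.
#' @export
dropRegions <- function(ai, pasteLog = NULL) {
  regions <- lapply(instances(ai), bbox)
  if (!is.null(pasteLog) && nrow(pasteLog)) {
    extra <- pasteLog[pasteLog$accepted & !pasteLog$labeled, , drop = FALSE]
    for (i in seq_len(nrow(extra)))
      regions[[length(regions) + 1L]] <-
        c(extra$x[i], extra$y[i], extra$w[i], extra$h[i])
  }
  regions
}
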