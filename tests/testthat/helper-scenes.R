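# Programmatic fixtures: tiny annotated scenes, prediction sets and crops.

# Disk mask helper mirroring the package's pixel-centre convention.
helperDisk <- function(h, w, cx, cy, r) {
  ys <- matrix(seq_len(h) - 0.5, h, w)
  xs <- matrix(rep(seq_len(w) - 0.5, each = h), h, w)
  (xs - cx)^2 + (ys - cy)^2 <= r^2
}

# Flat-background image with disk instances at given (cx, cy, r) rows.
helperDiskImage <- function(side, disks, imageId = 1L, bg = 0.2, fg = 0.8) {
  px <- matrix(bg, side, side)
  insts <- list()
  for (i in seq_len(nrow(disks))) {
    m <- helperDisk(side, side, disks[i, 1], disks[i, 2], disks[i, 3])
    px[m] <- fg
    insts[[i]] <- Instance(m, instanceId = i)
  }
  AnnotatedImage(px, imageId = imageId, instances = insts)
}

# Random small scene for metric tests: <=5 GT disks, <=8 predictions (jittered
# copies of GT plus spurious disks), random scores.
helperRandomEvalScene <- function(seed, side = 64L) {
  set.seed(seed)
  nGt <- sample(0:5, 1)
  disks <- matrix(numeric(0), ncol = 3)
  while (nrow(disks) < nGt) {
    cand <- c(runif(1, 8, side - 8), runif(1, 8, side - 8), runif(1, 3, 7))
    if (nrow(disks) == 0 ||
        all(sqrt((disks[, 1] - cand[1])^2 + (disks[, 2] - cand[2])^2) >
            disks[, 3] + cand[3] + 1))
      disks <- rbind(disks, cand)
  }
  ai <- if (nGt > 0) helperDiskImage(side, disks) else
    AnnotatedImage(matrix(0.2, side, side), imageId = 1L)
  nPred <- sample(0:8, 1)
  preds <- list()
  for (k in seq_len(nPred)) {
    if (nGt > 0 && runif(1) < 0.6) {      # jittered copy of a random GT
      g <- sample(nGt, 1)
      m <- helperDisk(side, side, disks[g, 1] + rnorm(1, 0, 2),
                      disks[g, 2] + rnorm(1, 0, 2),
                      disks[g, 3] * runif(1, 0.8, 1.2))
    } else {                               # spurious disk anywhere
      m <- helperDisk(side, side, runif(1, 6, side - 6), runif(1, 6, side - 6),
                      runif(1, 3, 7))
    }
    if (!any(m)) next
    preds[[length(preds) + 1L]] <- Prediction(m, score = runif(1), imageId = 1L)
  }
  list(image = ai, predictions = preds)
}

# Random scene for harvest tests: <=5 GT, <=5 predictions.
helperRandomHarvestScene <- function(seed, side = 64L) {
  sc <- helperRandomEvalScene(seed, side)
  sc$predictions <- sc$predictions[seq_len(min(5L, length(sc$predictions)))]
  sc
}

# Minimal RegionCrop of a given patch size, value-tagged for identification.
helperCrop <- function(h = 4L, w = 4L, value = 0.5, label = "eq1_zoo",
                       step = 0L) {
  RegionCrop(pixels = matrix(value, h, w), mask = matrix(TRUE, h, w),
             sourceImageId = 1L, sourceScore = 0.1, zooLabel = label,
             entryStep = step)
}

# Independent RLE oracle: walk the column-major vector and count runs.
helperRleOracle <- function(mask) {
  v <- as.integer(as.vector(mask != 0))
  counts <- integer(0)
  cur <- 0L; n <- 0L
  for (x in v) {
    if (x == cur) n <- n + 1L
    else { counts <- c(counts, n); cur <- x; n <- 1L }
  }
  c(counts, n)
}

# Independent set-algebra oracle for the two harvest rules: full-frame pixel
# index sets computed with which()/intersect()/setdiff().
helperHarvestOracle <- function(ai, preds, ct, gamma) {
  gtIdx <- integer(0)
  for (inst in instances(ai)) gtIdx <- union(gtIdx, which(binMask(inst)))
  eq1 <- list(); eq2 <- list()
  for (p in preds) {
    pIdx <- which(binMask(p))
    if (score(p) < ct) {
      inter <- intersect(pIdx, gtIdx)
      if (length(inter)) eq1[[length(eq1) + 1L]] <- sort(inter)
    }
    if (score(p) > ct) {
      ok <- TRUE
      for (inst in instances(ai)) {
        ratio <- length(intersect(pIdx, which(binMask(inst)))) / length(pIdx)
        if (ratio > gamma) { ok <- FALSE; break }
      }
      if (ok) {
        outside <- setdiff(pIdx, gtIdx)
        if (length(outside)) eq2[[length(eq2) + 1L]] <- sort(outside)
      }
    }
  }
  list(eq1 = eq1, eq2 = eq2)
}

# Full-frame pixel indices of a harvested crop (crop mask re-embedded at its
# source location found by matching the crop pixels is not possible in
# general; instead the harvest functions are fed scenes where the tight box
# is recoverable from the mask itself).
helperCropIndices <- function(crop, ai, candidateIdx) {
  # reconstruct by matching popcount + tight box against candidate sets
  for (cand in candidateIdx) {
    m <- matrix(FALSE, imageHeight(ai), imageWidth(ai)); m[cand] <- TRUE
    b <- tightBox(m)
    if (identical(dim(binMask(crop)), c(as.integer(b[4]), as.integer(b[3]))) &&
        identical(which(binMask(crop)), which(
          m[(b[2] + 1):(b[2] + b[4]), (b[1] + 1):(b[1] + b[3]), drop = FALSE])))
      return(cand)
  }
  NULL
}
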