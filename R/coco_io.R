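#' Encode a binary mask as COCO uncompressed RLE
#'
#' The mask is flattened in column-major (Fortran) order, matching the COCO
#' convention, and encoded as alternating run lengths starting with the number
#' of leading background pixels (possibly 0).
#'
#' @param mask logical (or 0/1) matrix.
#' @return list with `size = c(h, w)` and integer `counts`.
#' @seealso [rleDecode()]
#' @export
rleEncode <- function(mask) {
  mask <- asMask(mask)
  v <- as.integer(as.vector(mask))
  if (length(v) == 0L) return(list(size = dim(mask), counts = integer(0)))
  r <- rle(v)
  counts <- as.integer(r$lengths)
  if (r$values[1L] == 1L) counts <- c(0L, counts)
  list(size = as.integer(dim(mask)), counts = counts)
}

#' Decode COCO uncompressed RLE to a binary mask
#'
#' @param counts integer run lengths (leading run is background).
#' @param h,w mask dimensions.
#' @return logical `h x w` matrix.
#' @export
rleDecode <- function(counts, h, w) {
  counts <- as.integer(counts)
  vals <- rep(rep(c(FALSE, TRUE), length.out = length(counts)), counts)
  if (length(vals) != h * w)
    stop("RLE counts sum to ", length(vals), " pixels, expected ", h * w)
  matrix(vals, nrow = h, ncol = w)
}

#' Rasterise a COCO polygon to a binary mask
#'
#' Even-odd scanline fill at pixel centres: pixel (x, y) is foreground when its
#' centre (x + 0.5, y + 0.5) lies inside the polygon. `xy` is the flat COCO
#' coordinate list `[x1, y1, x2, y2, ...]` in 0-based pixel units.
#'
#' @param xy even-length numeric vector of vertices.
#' @param h,w output dimensions.
#' @return logical `h x w` matrix.
#' @export
polygonToMask <- function(xy, h, w) {
  stopifnot(length(xy) %% 2 == 0, length(xy) >= 6)
  px <- xy[seq(1, length(xy), 2)]
  py <- xy[seq(2, length(xy), 2)]
  n <- length(px)
  nxt <- c(2:n, 1)
  mask <- matrix(FALSE, h, w)
  rlo <- max(1L, floor(min(py)) ) ; rhi <- min(h, ceiling(max(py)) + 1L)
  for (r in rlo:rhi) {
    yc <- r - 0.5
    lo <- pmin(py, py[nxt]); hi <- pmax(py, py[nxt])
    act <- which(lo <= yc & yc < hi)   # half-open rule avoids double-counted vertices
    if (!length(act)) next
    xs <- px[act] + (yc - py[act]) * (px[nxt][act] - px[act]) / (py[nxt][act] - py[act])
    xs <- sort(xs)
    for (k in seq(1, length(xs) - 1, 2)) {
      c0 <- max(1L, ceiling(xs[k] + 0.5))
      c1 <- min(w, floor(xs[k + 1] + 0.5))
      if (c0 <= c1) mask[r, c0:c1] <- TRUE
    }
  }
  mask
}

#' Read a COCO dataset into AnnotatedImage objects
#'
#' Parses a COCO annotation JSON (`images` / `annotations` / `categories`) and
#' loads the referenced image files. Polygon and uncompressed-RLE segmentations
#' are both decoded to full-frame binary masks; boxes are taken as the tight
#' boxes of the decoded masks (a stored `bbox` deviating by more than 2 px
#' triggers a warning). 8-bit and 16-bit grayscale PNG/TIFF are accepted and
#' rescaled to [0, 1].
#'
#' Hard errors: a referenced image file that does not exist (named in the
#' error) and an annotation referencing an unknown `image_id`. Annotations
#' whose decoded mask is empty are skipped with a warning. Multi-category
#' files are collapsed to the single category with a warning.
#'
#' @param annotationPath path to the COCO JSON.
#' @param imageDir directory holding the image files named in `file_name`.
#' @return list of [AnnotatedImage-class], one per COCO image record.
#' @export
readCocoDataset <- function(annotationPath, imageDir) {
  coco <- jsonlite::fromJSON(annotationPath, simplifyVector = FALSE)
  cats <- vapply(coco$categories, function(ct) ct$id, numeric(1))
  annCats <- vapply(coco$annotations, function(a) a$category_id, numeric(1))
  if (length(unique(c(cats, annCats))) > 1L)
    warning("multi-category COCO file collapsed to single category 1")

  imgs <- list()
  for (rec in coco$images) {
    f <- file.path(imageDir, rec$file_name)
    if (!file.exists(f)) stop("missing image file: ", f)
    px <- fromEBImage(EBImage::readImage(f))
    imgs[[as.character(rec$id)]] <- AnnotatedImage(px, imageId = rec$id)
  }

  nextInstId <- integer(0)
  for (a in coco$annotations) {
    key <- as.character(a$image_id)
    if (is.null(imgs[[key]]))
      stop("annotation ", a$id, " references unknown image_id ", a$image_id)
    ai <- imgs[[key]]
    h <- imageHeight(ai); w <- imageWidth(ai)
    seg <- a$segmentation
    if (!is.null(seg$counts)) {
      mask <- rleDecode(unlist(seg$counts), unlist(seg$size)[1], unlist(seg$size)[2])
    } else {
      mask <- matrix(FALSE, h, w)
      for (poly in seg) mask <- mask | polygonToMask(unlist(poly), h, w)
    }
    if (!any(mask)) {
      warning("annotation ", a$id, " has an empty mask; skipped")
      next
    }
    tb <- tightBox(mask)
    if (!is.null(a$bbox) && max(abs(unlist(a$bbox) - tb)) > 2)
      warning("annotation ", a$id, ": stored bbox is not tight; recomputed")
    id <- length(instances(ai)) + 1L
    instances(ai) <- c(instances(ai), Instance(mask, box = tb, instanceId = id))
    imgs[[key]] <- ai
  }
  unname(imgs)
}

#' Write an AnnotatedImage dataset as PNG files plus a COCO JSON
#'
#' Masks are stored as uncompressed RLE, boxes as tight boxes, so a read-back
#' through [readCocoDataset()] is pixel-exact on masks. Pixel files are 8-bit
#' PNG (grayscale or colour).
#'
#' @param dataset list of [AnnotatedImage-class].
#' @param outDir output directory (created if needed).
#' @param annotationFile name of the JSON file inside `outDir`.
#' @return invisibly, the path of the annotation file.
#' @export
writeCocoDataset <- function(dataset, outDir, annotationFile = "annotations.json") {
  if (!dir.exists(outDir) && !dir.create(outDir, recursive = TRUE))
    stop("cannot create output directory: ", outDir)
  images <- list(); annotations <- list(); annId <- 0L
  for (ai in dataset) {
    fn <- sprintf("image_%06d.png", imageId(ai))
    EBImage::writeImage(toEBImage(clip01(pixels(ai))), file.path(outDir, fn))
    images[[length(images) + 1L]] <- list(
      id = imageId(ai), file_name = fn,
      width = imageWidth(ai), height = imageHeight(ai))
    for (inst in instances(ai)) {
      annId <- annId + 1L
      annotations[[annId]] <- list(
        id = annId, image_id = imageId(ai), category_id = classId(inst),
        bbox = bbox(inst), area = sum(binMask(inst)),
        segmentation = rleEncode(binMask(inst)), iscrowd = 0L)
    }
  }
  path <- file.path(outDir, annotationFile)
  jsonlite::write_json(
    list(images = images, annotations = annotations,
         categories = list(list(id = 1L, name = "hRS"))),
    path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Write predictions as COCO-style result JSON
#'
#' One record per prediction with `image_id`, `category_id`, `bbox`,
#' `segmentation` (uncompressed RLE) and `score`. Boxes and scores round-trip
#' bit-exactly, masks pixel-exactly, through [readPredictions()].
#'
#' @param predictions list of [Prediction-class].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
writePredictions <- function(predictions, path) {
  recs <- lapply(predictions, function(p) list(
    image_id = imageId(p), category_id = 1L, bbox = bbox(p),
    segmentation = rleEncode(binMask(p)), score = score(p)))
  out <- tryCatch(jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = I(17)),
                  error = function(e) stop("cannot write predictions to ", path,
                                           ": ", conditionMessage(e)))
  invisible(path)
}

#' Read a COCO-style result JSON back into Prediction objects
#'
#' @param path result JSON written by [writePredictions()] (or compatible).
#' @return list of [Prediction-class].
#' @export
readPredictions <- function(path) {
  recs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(recs, function(r) {
    sz <- unlist(r$segmentation$size)
    mask <- rleDecode(unlist(r$segmentation$counts), sz[1], sz[2])
    Prediction(mask, score = r$score, box = unlist(r$bbox),
               imageId = r$image_id)
  })
}

#' Subset-size arithmetic for an instance-count split
#'
#' `train = floor(r_train * total)`, `val = floor(r_val * total)`, and the
#' remainder goes to test, so the three sizes always sum to the total. With
#' the 80/10/10 ratios and 8003 instances this yields 6402 / 800 / 801.
#'
#' @param totalInstances non-negative integer.
#' @param ratios numeric(3), non-negative, summing to 1 (tolerance 1e-9).
#' @return integer(3) named train/val/test.
#' @export
computeSplitSizes <- function(totalInstances, ratios) {
  stopifnot(totalInstances >= 0, length(ratios) == 3L, all(ratios >= 0))
  if (abs(sum(ratios) - 1) > 1e-9)
    stop("split ratios must sum to 1 (got ", sum(ratios), ")")
  train <- floor(ratios[1] * totalInstances)
  val <- floor(ratios[2] * totalInstances)
  c(train = train, val = val, test = totalInstances - train - val)
}

#' Randomised image-granularity split targeting instance counts
#'
#' Images are shuffled with `seed` and assigned whole, each to the subset whose
#' realised instance count is furthest below its [computeSplitSizes()] target
#' (ties favour train, then val). This reproduces the target counts exactly
#' whenever the image instance counts permit, and degrades gracefully
#' otherwise. The same seed always yields the same assignment.
#'
#' @param dataset non-empty list of [AnnotatedImage-class].
#' @param ratios numeric(3) summing to 1.
#' @param seed integer RNG seed.
#' @return a [DatasetSplit-class].
#' @export
splitDataset <- function(dataset, ratios = c(0.8, 0.1, 0.1), seed = 1L) {
  stopifnot(length(dataset) > 0L)
  counts <- vapply(dataset, function(ai) length(instances(ai)), integer(1))
  ids <- vapply(dataset, imageId, integer(1))
  target <- computeSplitSizes(sum(counts), ratios)
  ord <- withSeed(seed, sample.int(length(dataset)))
  realized <- c(train = 0, val = 0, test = 0)
  subset <- character(length(dataset))
  for (i in ord) {
    deficit <- target - realized
    pick <- which.max(deficit)  # ties: first index, i.e. train > val > test
    subset[i] <- names(target)[pick]
    realized[pick] <- realized[pick] + counts[i]
  }
  new("DatasetSplit",
      trainSize = as.integer(realized["train"]),
      valSize = as.integer(realized["val"]),
      testSize = as.integer(realized["test"]),
      assignment = data.frame(imageId = ids, subset = subset,
                              nInstances = counts))
}
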