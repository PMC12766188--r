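#' @rdname accessors
setMethod("bbox", "Instance", function(x) x@box)
#' @rdname accessors
setMethod("bbox", "Prediction", function(x) x@box)
#' @rdname accessors
setMethod("bbox", "RegionCrop", function(x) tightBox(x@mask))

#' @rdname accessors
setMethod("binMask", "Instance", function(x) x@mask)
#' @rdname accessors
setMethod("binMask", "Prediction", function(x) x@mask)
#' @rdname accessors
setMethod("binMask", "RegionCrop", function(x) x@mask)

#' @rdname accessors
setMethod("score", "Prediction", function(x) x@score)
#' @rdname accessors
setMethod("imageId", "Prediction", function(x) x@imageId)
#' @rdname accessors
setMethod("imageId", "AnnotatedImage", function(x) x@imageId)
#' @rdname accessors
setMethod("classId", "Instance", function(x) x@classId)
#' @rdname accessors
setMethod("instanceId", "Instance", function(x) x@instanceId)

#' @rdname accessors
setMethod("pixels", "AnnotatedImage", function(x) x@pixels)
#' @rdname accessors
setMethod("pixels", "RegionCrop", function(x) x@pixels)
#' @rdname accessors
setReplaceMethod("pixels", "AnnotatedImage", function(x, value) {
  if (is.matrix(value)) value <- array(value, dim = dim(value))
  x@pixels <- value
  validObject(x)
  x
})

#' @rdname accessors
setMethod("instances", "AnnotatedImage", function(x) x@instances)
#' @rdname accessors
setReplaceMethod("instances", "AnnotatedImage", function(x, value) {
  x@instances <- value
  validObject(x)
  x
})

#' @rdname accessors
setMethod("imageWidth", "AnnotatedImage", function(x) dim(x@pixels)[2L])
#' @rdname accessors
setMethod("imageHeight", "AnnotatedImage", function(x) dim(x@pixels)[1L])

#' @rdname accessors
setMethod("zooEntries", "RegionZoo", function(x) x@entries)
#' @rdname accessors
setMethod("zooCapacity", "RegionZoo", function(x) x@capacity)
#' @rdname accessors
setMethod("zooSize", "RegionZoo", function(x) length(x@entries))
#' @rdname accessors
setMethod("zooLabel", "RegionCrop", function(x) x@zooLabel)
#' @rdname accessors
setMethod("entryStep", "RegionCrop", function(x) x@entryStep)

#' @rdname accessors
setMethod("bboxMAP", "EvalReport", function(x) x@bboxMap)
#' @rdname accessors
setMethod("maskMAP", "EvalReport", function(x) x@maskMap)
#' @rdname accessors
setMethod("perImageTerms", "EvalReport", function(x, mode = "bbox") {
  mode <- match.arg(mode, c("bbox", "mask"))
  if (mode == "bbox") x@perImageBbox else x@perImageMask
})

setMethod("show", "Instance", function(object) {
  b <- round(object@box, 2)
  cat(sprintf("Instance #%d (class %d): box [%s], mask %d px\n",
              object@instanceId, object@classId, paste(b, collapse = ", "),
              sum(object@mask)))
})

setMethod("show", "Prediction", function(object) {
  b <- round(object@box, 2)
  cat(sprintf("Prediction (image %d): score %.3f, box [%s], mask %d px\n",
              object@imageId, object@score, paste(b, collapse = ", "),
              sum(object@mask)))
})

setMethod("show", "AnnotatedImage", function(object) {
  d <- dim(object@pixels)
  ch <- if (length(d) == 3L) d[3L] else 1L
  cat(sprintf("AnnotatedImage #%d: %d x %d px, %d channel(s), %d instance(s)\n",
              object@imageId, d[2L], d[1L], ch, length(object@instances)))
})

setMethod("show", "RegionZoo", function(object) {
  cat(sprintf("RegionZoo: %d / %d entries", length(object@entries),
              object@capacity))
  if (length(object@entries)) {
    labs <- table(vapply(object@entries, zooLabel, character(1)))
    cat(" (", paste(names(labs), labs, sep = ": ", collapse = ", "), ")", sep = "")
  }
  cat("\n")
})

setMethod("show", "DatasetSplit", function(object) {
  cat(sprintf("DatasetSplit: %d / %d / %d instances (train/val/test) over %d images\n",
              object@trainSize, object@valSize, object@testSize,
              nrow(object@assignment)))
})

setMethod("show", "EvalReport", function(object) {
  cat(sprintf(paste0("EvalReport: bbox mAP %.4f, mask mAP %.4f ",
                     "(%d images, %d predictions, %d ground-truth instances)\n"),
              object@bboxMap, object@maskMap, object@nImages,
              object@nPredictions, object@nGt))
})
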