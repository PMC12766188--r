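#' Accessor generics
#'
#' Small accessor layer over the S4 containers: `bbox()`, `binMask()`,
#' `score()`, `imageId()`, `classId()`, `instanceId()`, `pixels()`,
#' `instances()`, `imageWidth()`/`imageHeight()`, `zooEntries()`,
#' `zooCapacity()`, `zooSize()`, `zooLabel()`, `entryStep()`, `bboxMAP()`,
#' `maskMAP()`, `perImageTerms()`.
#'
#' @param x an object from this package.
#' @param value replacement value.
#' @param mode for `perImageTerms`, `"bbox"` or `"mask"`.
#' @return the slot contents (or, for `zooSize`, the current entry count).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("bbox", function(x) standardGeneric("bbox"))
#' @rdname accessors
#' @export
setGeneric("binMask", function(x) standardGeneric("binMask"))
#' @rdname accessors
#' @export
setGeneric("score", function(x) standardGeneric("score"))
#' @rdname accessors
#' @export
setGeneric("imageId", function(x) standardGeneric("imageId"))
#' @rdname accessors
#' @export
setGeneric("classId", function(x) standardGeneric("classId"))
#' @rdname accessors
#' @export
setGeneric("instanceId", function(x) standardGeneric("instanceId"))
#' @rdname accessors
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))
#' @rdname accessors
#' @export
setGeneric("pixels<-", function(x, value) standardGeneric("pixels<-"))
#' @rdname accessors
#' @export
setGeneric("instances", function(x) standardGeneric("instances"))
#' @rdname accessors
#' @export
setGeneric("instances<-", function(x, value) standardGeneric("instances<-"))
#' @rdname accessors
#' @export
setGeneric("imageWidth", function(x) standardGeneric("imageWidth"))
#' @rdname accessors
#' @export
setGeneric("imageHeight", function(x) standardGeneric("imageHeight"))
#' @rdname accessors
#' @export
setGeneric("zooEntries", function(x) standardGeneric("zooEntries"))
#' @rdname accessors
#' @export
setGeneric("zooCapacity", function(x) standardGeneric("zooCapacity"))
#' @rdname accessors
#' @export
setGeneric("zooSize", function(x) standardGeneric("zooSize"))
#' @rdname accessors
#' @export
setGeneric("zooLabel", function(x) standardGeneric("zooLabel"))
#' @rdname accessors
#' @export
setGeneric("entryStep", function(x) standardGeneric("entryStep"))
#' @rdname accessors
#' @export
setGeneric("bboxMAP", function(x) standardGeneric("bboxMAP"))
#' @rdname accessors
#' @export
setGeneric("maskMAP", function(x) standardGeneric("maskMAP"))
#' @rdname accessors
#' @export
setGeneric("perImageTerms", function(x, mode = "bbox") standardGeneric("perImageTerms"))
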