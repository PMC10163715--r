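#' @rdname AlleleCounts
#' @param x an object.
#' @export
setGeneric("zCave", function(x) standardGeneric("zCave"))

#' @rdname AlleleCounts
#' @export
setGeneric("zSurface", function(x) standardGeneric("zSurface"))

#' @rdname AlleleCounts
#' @export
setGeneric("totalCounts", function(x) standardGeneric("totalCounts"))

#' @rdname AlleleCounts
#' @export
setGeneric("alleleRatio", function(x) standardGeneric("alleleRatio"))

#' @rdname TranscriptPairSet
#' @param x an object.
#' @export
setGeneric("caveSeqs", function(x) standardGeneric("caveSeqs"))

#' @rdname TranscriptPairSet
#' @export
setGeneric("surfaceSeqs", function(x) standardGeneric("surfaceSeqs"))

#' @rdname TranscriptPairSet
#' @export
setGeneric("pairIds", function(x) standardGeneric("pairIds"))

#' @rdname TranscriptPairSet
#' @export
setGeneric("pairInfo", function(x) standardGeneric("pairInfo"))

#' @rdname TranscriptPairSet
#' @param pair a pair id.
#' @export
setGeneric("coordMap", function(x, pair) standardGeneric("coordMap"))
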