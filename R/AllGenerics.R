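# Accessor generics. Slots are never reached into by user code.

#' Length of the resolved direct terminal repeat
#' @param x A \linkS4class{DTRAnnotation}, \linkS4class{TruthSet} or
#'   \linkS4class{SimulationConfig}.
#' @return Integer repeat length in bp.
#' @export
setGeneric("dtrLength", function(x) standardGeneric("dtrLength"))

#' @rdname dtrLength
#' @export
setMethod("dtrLength", "DTRAnnotation", function(x) x@dtrLength)
#' @rdname dtrLength
#' @export
setMethod("dtrLength", "TruthSet", function(x) x@dtrLength)
#' @rdname dtrLength
#' @export
setMethod("dtrLength", "SimulationConfig", function(x) x@dtrLength)

#' Per-position depth of a profile
#' @param x A \linkS4class{DepthProfile}.
#' @return Integer vector of per-position depth.
#' @export
setGeneric("depthValues", function(x) standardGeneric("depthValues"))
#' @rdname depthValues
#' @export
setMethod("depthValues", "DepthProfile", function(x) x@depth)

#' Median-normalized depth of a profile
#' @param x A \linkS4class{DepthProfile}.
#' @return Numeric vector \code{depth / median(depth)}.
#' @export
setGeneric("normalizedDepth", function(x) standardGeneric("normalizedDepth"))
#' @rdname normalizedDepth
#' @export
setMethod("normalizedDepth", "DepthProfile", function(x) {
  if (x@medianDepth <= 0)
    stop("cannot normalize a profile with median depth 0")
  x@depth / x@medianDepth
})

#' Alignment records as a data.frame
#' @param x A \linkS4class{PhageAlignments}.
#' @return data.frame of alignment records (0-based \code{ref_start}).
#' @export
setGeneric("alignmentData", function(x) standardGeneric("alignmentData"))
#' @rdname alignmentData
#' @export
setMethod("alignmentData", "PhageAlignments", function(x) x@data)

#' Reference lengths known to an alignment set
#' @param x A \linkS4class{PhageAlignments}.
#' @return Named integer vector of reference lengths.
#' @export
setGeneric("referenceLengths", function(x) standardGeneric("referenceLengths"))
#' @rdname referenceLengths
#' @export
setMethod("referenceLengths", "PhageAlignments", function(x) x@seqinfo)

#' Truth genome sequence
#' @param x A \linkS4class{TruthSet}.
#' @return Character scalar genome sequence.
#' @export
setGeneric("genomeSeq", function(x) standardGeneric("genomeSeq"))
#' @rdname genomeSeq
#' @export
setMethod("genomeSeq", "TruthSet", function(x) x@seq)

#' Ordered edit actions recorded in a curation report
#' @param x A \linkS4class{CurationReport}.
#' @return List of edit records.
#' @export
setGeneric("curationActions", function(x) standardGeneric("curationActions"))
#' @rdname curationActions
#' @export
setMethod("curationActions", "CurationReport", function(x) x@actions)

#' Number of alignment records
#' @param x A \linkS4class{PhageAlignments}.
#' @export
setMethod("length", "PhageAlignments", function(x) nrow(x@data))
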