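#' @rdname accessors
#' @export
setGeneric("abundanceScale", function(x) standardGeneric("abundanceScale"))

#' @rdname accessors
#' @export
setGeneric("appliedSteps", function(x) standardGeneric("appliedSteps"))

#' @rdname accessors
#' @export
setGeneric("channelInfo", function(x) standardGeneric("channelInfo"))

#' @rdname accessors
#' @export
setGeneric("plexId", function(x) standardGeneric("plexId"))

#' @rdname accessors
#' @export
setGeneric("designChannels", function(x) standardGeneric("designChannels"))

#' @rdname accessors
#' @export
setGeneric("ptmKind", function(x) standardGeneric("ptmKind"))

#' @rdname accessors
#' @export
setGeneric("isProteinAdjusted",
           function(x) standardGeneric("isProteinAdjusted"))

#' @rdname accessors
#' @export
setGeneric("missingMask", function(x) standardGeneric("missingMask"))

#' Accessors for redoxomics containers
#'
#' Small accessor layer over the S4 slots: the measurement scale and the
#' applied-step provenance of an \linkS4class{OmicsMatrix}, the channel
#' metadata table, the PTM kind and protein-adjustment state of a
#' \linkS4class{SiteMatrix}, the missingness mask of a
#' \linkS4class{LipidMatrix}, and the id/channel table of a
#' \linkS4class{PlexDesign}.
#'
#' @param x a redoxomics object.
#' @return the corresponding slot value; \code{channelInfo} returns the
#'   column metadata as a data.frame.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("abundanceScale", "OmicsMatrix", function(x) x@scale)

#' @rdname accessors
#' @export
setMethod("appliedSteps", "OmicsMatrix", function(x) x@appliedSteps)

#' @rdname accessors
#' @export
setMethod("channelInfo", "OmicsMatrix",
          function(x) as.data.frame(SummarizedExperiment::colData(x)))

#' @rdname accessors
#' @export
setMethod("plexId", "PlexDesign", function(x) x@plexId)

#' @rdname accessors
#' @export
setMethod("designChannels", "PlexDesign", function(x) x@channels)

#' @rdname accessors
#' @export
setMethod("ptmKind", "SiteMatrix", function(x) x@ptmKind)

#' @rdname accessors
#' @export
setMethod("isProteinAdjusted", "SiteMatrix",
          function(x) x@adjustedForProtein)

#' @rdname accessors
#' @export
setMethod("missingMask", "LipidMatrix", function(x) x@missingMask)
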