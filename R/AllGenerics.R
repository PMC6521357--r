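#' @rdname Methylome-class
#' @param x A \linkS4class{Methylome}.
#' @export
setGeneric("sites", function(x) standardGeneric("sites"))

#' @rdname Methylome-class
#' @export
setMethod("sites", "Methylome", function(x) x@sites)

#' @rdname Methylome-class
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))

#' @rdname Methylome-class
#' @export
setMethod("sampleId", "Methylome", function(x) x@sampleId)

#' @rdname Methylome-class
#' @export
setGeneric("methContext", function(x) standardGeneric("methContext"))

#' @rdname Methylome-class
#' @export
setMethod("methContext", "Methylome", function(x) x@context)

#' @rdname Methylome-class
#' @export
setMethod("length", "Methylome", function(x) length(x@sites))

#' @rdname TrainedModel-class
#' @param x A \linkS4class{TrainedModel}.
#' @export
setGeneric("modelWeights", function(x) standardGeneric("modelWeights"))

#' @rdname TrainedModel-class
#' @export
setMethod("modelWeights", "TrainedModel", function(x) x@weights)

#' @rdname TrainedModel-class
#' @export
setGeneric("featureParams", function(x) standardGeneric("featureParams"))

#' @rdname TrainedModel-class
#' @export
setMethod("featureParams", "TrainedModel", function(x) x@params)

#' @rdname TrainedModel-class
#' @export
setMethod("methContext", "TrainedModel", function(x) x@context)
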