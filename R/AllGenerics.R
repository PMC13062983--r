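#' @export
setGeneric("cdData", function(x) standardGeneric("cdData"))

#' @export
setGeneric("embryoId", function(x) standardGeneric("embryoId"))

#' @export
setGeneric("embryoId<-", function(x, value) standardGeneric("embryoId<-"))

#' @export
setGeneric("coordUnits", function(x) standardGeneric("coordUnits"))

#' @export
setGeneric("timeUnits", function(x) standardGeneric("timeUnits"))

#' @export
setGeneric("exprColumns", function(x) standardGeneric("exprColumns"))

#' @export
setGeneric("cellNames", function(x) standardGeneric("cellNames"))

#' @export
setGeneric("timePoints", function(x) standardGeneric("timePoints"))

#' @export
setGeneric("decayRate", function(x) standardGeneric("decayRate"))

#' @export
setGeneric("referenceDepth", function(x) standardGeneric("referenceDepth"))

#' @export
setGeneric("alignmentOffsets", function(x) standardGeneric("alignmentOffsets"))

#' @export
setGeneric("treeCells", function(x) standardGeneric("treeCells"))
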