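#' @export
setGeneric("scores", function(x, ...) standardGeneric("scores"))

#' @export
setGeneric("itemInfo", function(x) standardGeneric("itemInfo"))

#' @export
setGeneric("caseIDs", function(x) standardGeneric("caseIDs"))

#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' @export
setGeneric("variantInfo", function(x) standardGeneric("variantInfo"))

#' @export
setGeneric("mafs", function(x) standardGeneric("mafs"))

#' @export
setGeneric("callRates", function(x) standardGeneric("callRates"))

#' @export
setGeneric("discriminations", function(x) standardGeneric("discriminations"))

#' @export
setGeneric("thresholds", function(x) standardGeneric("thresholds"))

#' @export
setGeneric("posteriorSD", function(x) standardGeneric("posteriorSD"))

#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))
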