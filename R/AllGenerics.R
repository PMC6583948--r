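#' @export
setGeneric("rarefy", function(x, depth, seed = NULL, ...)
  standardGeneric("rarefy"))

#' @export
setGeneric("taxonStats", function(x, d = NULL, ...)
  standardGeneric("taxonStats"))

#' @export
setGeneric("classifyTaxa", function(fit, ...)
  standardGeneric("classifyTaxa"))

#' @export
setGeneric("otuCounts", function(x) standardGeneric("otuCounts"))

#' @export
setGeneric("taxonomy", function(x) standardGeneric("taxonomy"))

#' @export
setGeneric("immigrationRate", function(x) standardGeneric("immigrationRate"))

#' @export
setGeneric("goodnessOfFit", function(x) standardGeneric("goodnessOfFit"))
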