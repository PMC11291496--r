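#' @include AllClasses.R
NULL

#' @export
setGeneric("sampleData", function(object, ...) standardGeneric("sampleData"))

#' @export
setGeneric("asvProk", function(object) standardGeneric("asvProk"))

#' @export
setGeneric("asvFungi", function(object) standardGeneric("asvFungi"))

#' @export
setGeneric("geneTable", function(object) standardGeneric("geneTable"))

#' @export
setGeneric("incubations", function(object) standardGeneric("incubations"))

#' @export
setGeneric("aminoSugars", function(object) standardGeneric("aminoSugars"))

#' @export
setGeneric("fractionRecords", function(object) standardGeneric("fractionRecords"))

#' @export
setGeneric("rhSeries", function(object) standardGeneric("rhSeries"))

#' @export
setGeneric("minDepth", function(object) standardGeneric("minDepth"))

#' @export
setGeneric("rarefyTable", function(object, depth, seed) standardGeneric("rarefyTable"))

#' @export
setGeneric("topology", function(object, ...) standardGeneric("topology"))

#' @export
setGeneric("moduleMembership", function(object) standardGeneric("moduleMembership"))

#' @export
setGeneric("relativeModularity", function(object) standardGeneric("relativeModularity"))
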