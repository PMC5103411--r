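#' @export
setGeneric("nodeIds", function(x) standardGeneric("nodeIds"))

#' @export
setGeneric("adjacency", function(x) standardGeneric("adjacency"))

#' @export
setGeneric("numNodes", function(x) standardGeneric("numNodes"))

#' @export
setGeneric("diseaseNetwork", function(x) standardGeneric("diseaseNetwork"))

#' @export
setGeneric("diseaseDegrees", function(x) standardGeneric("diseaseDegrees"))

#' @export
setGeneric("molecularNetworks", function(x) standardGeneric("molecularNetworks"))

#' @export
setGeneric("seedVectors", function(x) standardGeneric("seedVectors"))

#' @export
setGeneric("centerNetworks", function(x) standardGeneric("centerNetworks"))

#' @export
setGeneric("auxNetworks", function(x, disease) standardGeneric("auxNetworks"))

#' @export
setGeneric("numAuxiliaries", function(x) standardGeneric("numAuxiliaries"))

#' @export
setGeneric("validateNoN", function(x) standardGeneric("validateNoN"))

#' @export
setGeneric("setSeeds", function(x, associations) standardGeneric("setSeeds"))

#' @export
setGeneric("scoreVectors", function(x) standardGeneric("scoreVectors"))

#' @export
setGeneric("concatScores", function(x) standardGeneric("concatScores"))
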