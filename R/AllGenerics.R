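#' @rdname PQRDataSet-class
#' @param x A `PQRDataSet` or `PQRBackground`.
#' @export
setGeneric("quantMatrix", function(x) standardGeneric("quantMatrix"))

#' @rdname PQRDataSet-class
#' @export
setGeneric("interactionPairs", function(x) standardGeneric("interactionPairs"))

#' @rdname PQRDataSet-class
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))

#' @rdname PQRDataSet-class
#' @export
setGeneric("referenceSamples", function(x) standardGeneric("referenceSamples"))

#' @rdname PQRDataSet-class
#' @export
setGeneric("testSamples", function(x) standardGeneric("testSamples"))

#' @rdname PQRBackground-class
#' @export
setGeneric("backgroundScores", function(x) standardGeneric("backgroundScores"))

#' @rdname PQRBackground-class
#' @export
setGeneric("gammaShape", function(x) standardGeneric("gammaShape"))

#' @rdname PQRBackground-class
#' @export
setGeneric("gammaRate", function(x) standardGeneric("gammaRate"))

#' @describeIn PQRDataSet-class The log-abundance assay matrix.
#' @export
setMethod("quantMatrix", "PQRDataSet", function(x)
  SummarizedExperiment::assay(x, "logAbundance"))

#' @describeIn PQRDataSet-class The deduplicated pair table.
#' @export
setMethod("interactionPairs", "PQRDataSet", function(x) x@interactionPairs)

#' @describeIn PQRDataSet-class Factor of sample group assignments.
#' @export
setMethod("sampleGroups", "PQRDataSet", function(x) {
  grp <- as.character(SummarizedExperiment::colData(x)$group)
  factor(grp, levels = c("reference", "test"))
})

#' @describeIn PQRDataSet-class Identifiers of reference samples.
#' @export
setMethod("referenceSamples", "PQRDataSet", function(x)
  colnames(x)[which(sampleGroups(x) == "reference")])

#' @describeIn PQRDataSet-class Identifiers of test samples.
#' @export
setMethod("testSamples", "PQRDataSet", function(x)
  colnames(x)[which(sampleGroups(x) == "test")])

#' @describeIn PQRBackground-class Vector of background pair scores.
#' @param x A `PQRBackground`.
#' @export
setMethod("backgroundScores", "PQRBackground", function(x) x@scores)

#' @describeIn PQRBackground-class Fitted gamma shape.
#' @export
setMethod("gammaShape", "PQRBackground", function(x) x@shape)

#' @describeIn PQRBackground-class Fitted gamma rate.
#' @export
setMethod("gammaRate", "PQRBackground", function(x) x@rate)
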