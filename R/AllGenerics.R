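#' @rdname SampleRegistry
#' @param object,x an object.
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname SampleRegistry
#' @export
setGeneric("popLabels", function(x) standardGeneric("popLabels"))

#' @rdname SampleRegistry
#' @export
setGeneric("sourcePopulation", function(x) standardGeneric("sourcePopulation"))

#' @rdname SampleRegistry
#' @export
setGeneric("derivedPopulations",
           function(x) standardGeneric("derivedPopulations"))

#' @rdname EigenResult
#' @param x an object with an eigen spectrum.
#' @export
setGeneric("eigenValues", function(x) standardGeneric("eigenValues"))

#' @rdname EigenResult
#' @export
setGeneric("eigenVectors", function(x) standardGeneric("eigenVectors"))

#' @rdname AlleleFreqTable
#' @export
setGeneric("freqMatrix", function(x) standardGeneric("freqMatrix"))

#' @rdname AlleleFreqTable
#' @export
setGeneric("sourceFreqs", function(x) standardGeneric("sourceFreqs"))
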