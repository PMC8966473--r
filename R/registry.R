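#' Construct a sample registry
#'
#' @param samples character vector of sample ids.
#' @param populations parallel character vector of population labels.
#' @param sourcePop the label of the source (founder) population.
#' @return a [SampleRegistry].
#' @examples
#' SampleRegistry(c("a", "b"), c("SRC", "P1"), sourcePop = "SRC")
#' @export
SampleRegistry <- function(samples, populations, sourcePop) {
  new("SampleRegistry", samples = as.character(samples),
      populations = as.character(populations),
      sourcePop = as.character(sourcePop))
}

#' Read a population map
#'
#' Reads a two-column (sample, population) whitespace- or tab-delimited file
#' and builds a [SampleRegistry] with the named source population.
#'
#' @param path path to the popmap file; no header expected.
#' @param sourcePop population label to flag as the source.
#' @return a [SampleRegistry].
#' @export
readPopmap <- function(path, sourcePop) {
  if (!file.exists(path)) stop("popmap file not found: ", path)
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("sample", "population"))
  if (anyDuplicated(tab$sample))
    stop("duplicate sample in popmap: ",
         tab$sample[duplicated(tab$sample)][1L])
  if (!sourcePop %in% tab$population)
    stop("source population '", sourcePop, "' not present in popmap")
  SampleRegistry(tab$sample, tab$population, sourcePop)
}

#' @rdname SampleRegistry
#' @export
setMethod("sampleIds", "SampleRegistry", function(x) x@samples)

#' @rdname SampleRegistry
#' @export
setMethod("popLabels", "SampleRegistry", function(x) x@populations)

#' @rdname SampleRegistry
#' @export
setMethod("sourcePopulation", "SampleRegistry", function(x) x@sourcePop)

#' @rdname SampleRegistry
#' @export
setMethod("derivedPopulations", "SampleRegistry", function(x)
  setdiff(unique(x@populations), x@sourcePop))

#' @rdname SampleRegistry
#' @export
setMethod("length", "SampleRegistry", function(x) length(x@samples))

setMethod("show", "SampleRegistry", function(object) {
  counts <- table(object@populations)
  cat("SampleRegistry:", length(object@samples), "samples in",
      length(counts), "populations\n")
  cat("  source:", object@sourcePop, "\n")
  cat("  sizes:", paste(names(counts), counts, sep = "=", collapse = ", "),
      "\n")
})

# sample column indices per population, in a fixed population order
popIndexList <- function(registry, samples) {
  idx <- match(registry@samples, samples)
  if (anyNA(idx))
    stop("sample in registry absent from genotype data: ",
         registry@samples[which(is.na(idx))[1L]])
  split(idx, registry@populations)
}
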