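#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<-
#' @importFrom GenomicRanges GRanges seqnames
#' @importFrom IRanges IRanges start end
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowRanges
#'   rowData colData
NULL

#' Sample-to-population registry
#'
#' Maps every sequenced sample to a population and flags exactly one
#' population as the source (founder) population from which all derived
#' populations were introduced.
#'
#' @slot samples character vector of unique sample identifiers.
#' @slot populations character vector, parallel to `samples`, giving each
#'   sample's population label.
#' @slot sourcePop single population label marking the source population.
#' @export
setClass("SampleRegistry",
  representation(samples = "character", populations = "character",
                 sourcePop = "character"))

setValidity("SampleRegistry", function(object) {
  msg <- NULL
  if (length(object@samples) != length(object@populations))
    msg <- c(msg, "samples and populations differ in length")
  if (anyDuplicated(object@samples))
    msg <- c(msg, sprintf("duplicate sample id: %s",
                          object@samples[duplicated(object@samples)][1L]))
  if (length(object@sourcePop) != 1L)
    msg <- c(msg, "exactly one source population must be flagged")
  else if (!object@sourcePop %in% object@populations)
    msg <- c(msg, sprintf("source population '%s' has no samples",
                          object@sourcePop))
  if (any(tabulate(factor(object@populations)) < 1L))
    msg <- c(msg, "every population needs at least one sample")
  if (is.null(msg)) TRUE else msg
})

#' Genotype matrix with genomic coordinates
#'
#' A [SummarizedExperiment::RangedSummarizedExperiment] holding biallelic SNP
#' genotypes as alternate-allele dosages (0/1/2, `NA` for missing) in the
#' `"GT"` assay; `rowRanges` carries chromosome/position (width-1 ranges) with
#' `REF` and `ALT` alleles in `rowData`.
#'
#' @export
setClass("GenotypeData", contains = "RangedSummarizedExperiment")

setValidity("GenotypeData", function(object) {
  if (!"GT" %in% SummarizedExperiment::assayNames(object))
    return("assay 'GT' is required")
  gt <- assay(object, "GT")
  bad <- gt[!is.na(gt)]
  if (length(bad) && (any(bad < 0L) || any(bad > 2L)))
    return("genotype dosages must be 0, 1, 2 or NA")
  if (!all(c("REF", "ALT") %in% colnames(rowData(object))))
    return("rowData must contain REF and ALT")
  TRUE
})

#' Polarized per-population allele-frequency table
#'
#' A [SummarizedExperiment::RangedSummarizedExperiment] with one column per
#' population. Assay `"freq"` is the frequency of the polarized allele (the
#' allele that is minor in the source population); assay `"nChr"` is the
#' number of non-missing chromosomes behind each estimate. `rowData` records
#' which allele was chosen (`polarized` is `"REF"` or `"ALT"`), and
#' `metadata()` carries `sourcePop` and the call-rate filter used.
#'
#' @export
setClass("AlleleFreqTable", contains = "RangedSummarizedExperiment")

setValidity("AlleleFreqTable", function(object) {
  if (!all(c("freq", "nChr") %in% SummarizedExperiment::assayNames(object)))
    return("assays 'freq' and 'nChr' are required")
  f <- assay(object, "freq")
  if (length(f) && (min(f) < 0 || max(f) > 1))
    return("frequencies must lie in [0, 1]")
  if (is.null(metadata(object)$sourcePop))
    return("metadata()$sourcePop is required")
  TRUE
})

#' One window of allele-frequency-change vectors
#'
#' Holds the m x n matrix X for a single genomic window: one row per derived
#' population (the change vector against the source), one column per SNP.
#'
#' @slot chrom chromosome the window lies on.
#' @slot startBp,endBp positions of the first and last SNP in the window.
#' @slot snpIdx integer indices of the window's SNPs in the parent frequency
#'   table.
#' @slot X numeric matrix, rows named by derived population.
#' @slot normalized `TRUE` once rows have been scaled to unit length.
#' @slot usable `FALSE` when a row was all-zero, making a direction of change
#'   undefined; such windows are excluded from eigenanalysis.
#' @export
setClass("DeltaAFWindow",
  representation(chrom = "character", startBp = "integer", endBp = "integer",
                 snpIdx = "integer", X = "matrix", normalized = "logical",
                 usable = "logical"))

setValidity("DeltaAFWindow", function(object) {
  X <- object@X
  if (!object@normalized && length(X) && (min(X) < -1 || max(X) > 1))
    return("raw allele-frequency changes must lie in [-1, 1]")
  if (object@normalized && object@usable) {
    norms <- sqrt(rowSums(X^2))
    if (any(abs(norms - 1) > 1e-12))
      return("normalized rows must have unit Euclidean length")
  }
  TRUE
})

#' Eigendecomposition of one window's correlation matrix
#'
#' Eigenvalues (descending) and orthonormal loadings of C = XX' for a single
#' window of row-normalized allele-frequency-change vectors. The sign of each
#' eigenvector is fixed so the first population's loading is non-negative.
#'
#' @slot chrom,startBp,endBp,snpIdx window identity (see [DeltaAFWindow]).
#' @slot values numeric eigenvalues, sorted descending; they sum to m.
#' @slot vectors m x m loading matrix, one column per eigenvector, rows named
#'   by derived population.
#' @export
setClass("EigenResult",
  representation(chrom = "character", startBp = "integer", endBp = "integer",
                 snpIdx = "integer", values = "numeric", vectors = "matrix"))

setValidity("EigenResult", function(object) {
  m <- length(object@values)
  if (any(diff(object@values) > 1e-12))
    return("eigenvalues must be sorted descending")
  if (any(object@values < -1e-10))
    return("eigenvalues must be non-negative (within tolerance)")
  if (abs(sum(object@values) - m) > 1e-8)
    return("eigenvalues must sum to the number of populations")
  G <- crossprod(object@vectors)
  if (max(abs(G - diag(m))) > 1e-8)
    return("loading vectors must be orthonormal")
  TRUE
})

#' Eigenanalysis results for all windows of a genome scan
#'
#' Container for the per-window eigenvalues, first-eigenvector loadings and
#' parallel/antiparallel direction calls of a whole-genome scan, plus the full
#' loading matrices for follow-up on higher eigenvectors.
#'
#' @slot windows `DataFrame` with one row per analysed window (chrom, startBp,
#'   endBp, nSnps, lambda columns, eigenvector-1 loadings, direction label).
#' @slot vectors list of m x m loading matrices, one per window.
#' @slot m number of derived populations.
#' @slot snpsPerWindow window size in SNPs.
#' @slot dropped number of windows excluded (all-zero change vector).
#' @export
setClass("EigenScan",
  representation(windows = "DataFrame", vectors = "list", m = "integer",
                 snpsPerWindow = "integer", dropped = "integer"))

#' Permutation null distribution of window eigenvalue statistics
#'
#' Stores, for each of `nPerms` label-shuffled random windows, the descending
#' eigenvalues of the permuted window's C matrix. The test statistic for
#' eigenvector k is lambda_1 for k = 1 and the cumulative sum
#' lambda_1 + ... + lambda_k for k > 1 (see [nullStatistics]).
#'
#' @slot values nPerms x m matrix of eigenvalues, rows descending.
#' @slot m,snpsPerWindow dimensions the null was built with.
#' @slot seed integer seed used.
#' @slot redraws number of windows redrawn (chromosome-boundary crossings or
#'   degenerate all-zero rows).
#' @export
setClass("NullDistribution",
  representation(values = "matrix", m = "integer", snpsPerWindow = "integer",
                 seed = "integer", redraws = "integer"))

setValidity("NullDistribution", function(object) {
  if (ncol(object@values) != object@m)
    return("one eigenvalue column per population is required")
  if (length(object@values) && min(object@values) < -1e-10)
    return("null eigenvalues must be non-negative")
  TRUE
})

#' Per-generation census trajectory of one population
#'
#' Drives the Wright-Fisher drift simulation: `sizes[t]` is the (diploid)
#' census size at generation t after founding, so generation 1 is the founding
#' bottleneck and `tau = length(sizes)` generations separate founding from
#' sampling.
#'
#' @slot population population label.
#' @slot n0 founding size (diploid individuals) recorded for reference.
#' @slot sizes integer vector N_1 ... N_tau.
#' @export
setClass("CensusTrajectory",
  representation(population = "character", n0 = "integer", sizes = "integer"))

setValidity("CensusTrajectory", function(object) {
  if (length(object@sizes) < 1L) return("tau must be at least 1 generation")
  if (any(object@sizes < 1L) || object@n0 < 1L)
    return("all census sizes must be at least 1")
  TRUE
})

#' A batch of replicate Wright-Fisher simulations
#'
#' @slot population population label simulated.
#' @slot founding numeric vector of founding frequencies, one per SNP.
#' @slot final replicates x SNPs matrix of frequencies at generation tau.
#' @slot tau generations simulated.
#' @slot seed integer seed used.
#' @export
setClass("SimulationBatch",
  representation(population = "character", founding = "numeric",
                 final = "matrix", tau = "integer", seed = "integer"))

setValidity("SimulationBatch", function(object) {
  if (ncol(object@final) != length(object@founding))
    return("one column per founding frequency is required")
  if (length(object@final) &&
      (min(object@final) < 0 || max(object@final) > 1))
    return("frequencies must lie in [0, 1]")
  TRUE
})

#' Neutral thresholds for summed selection coefficients
#'
#' Quantiles of the pooled neutral distribution of per-SNP summed selection
#' coefficients, computed from census-conditioned drift simulations.
#'
#' @slot thresholds numeric thresholds named by tail probability.
#' @slot probs the quantile levels.
#' @slot twoSided `TRUE` when quantiles are taken on |summed s|.
#' @slot tau generations used in the s computation.
#' @slot clamp frequency floor applied to fixed simulated frequencies.
#' @slot nValues number of pooled null values behind the quantiles.
#' @export
setClass("SummedSNull",
  representation(thresholds = "numeric", probs = "numeric",
                 twoSided = "logical", tau = "numeric", clamp = "numeric",
                 nValues = "integer"))

#' Design of a synthetic metapopulation dataset
#'
#' Fully specifies a simulated one-source, m-introduction study: sample sizes,
#' SNP layout, founder frequency spectrum, per-population census trajectories,
#' and optionally selected loci with their true selection coefficients and
#' sign patterns.
#'
#' @slot nDerived number of derived (introduced) populations, m >= 2.
#' @slot samplesPerPop diploid samples sequenced per population (source and
#'   derived alike).
#' @slot snpsPerChrom integer vector: SNPs on each chromosome.
#' @slot bpPerSnp average spacing used to draw SNP positions.
#' @slot founderNe effective size shaping the neutral founder frequency
#'   spectrum (see [sampleFounderFrequencies]).
#' @slot census list of [CensusTrajectory], one per derived population.
#' @slot selected `data.frame` with columns `snp` (global SNP index) and one
#'   `s_<pop>` column per derived population (signed selection coefficient on
#'   the founder-tracked allele); zero rows for a neutral design.
#' @slot selectedFounderFreq founder frequency pinned at the selected loci
#'   (recycled); length zero draws them from the spectrum like neutral sites.
#' @slot missingness probability an individual genotype call is missing.
#' @export
setClass("SyntheticDesign",
  representation(nDerived = "integer", samplesPerPop = "integer",
                 snpsPerChrom = "integer", bpPerSnp = "integer",
                 founderNe = "integer", census = "list",
                 selected = "data.frame",
                 selectedFounderFreq = "numeric",
                 missingness = "numeric"))

setValidity("SyntheticDesign", function(object) {
  if (object@nDerived < 2L) return("at least 2 derived populations required")
  if (length(object@census) != object@nDerived)
    return("one census trajectory per derived population is required")
  if (object@missingness < 0 || object@missingness >= 1)
    return("missingness must lie in [0, 1)")
  if (nrow(object@selected)) {
    if (any(object@selected$snp < 1L) ||
        any(object@selected$snp > sum(object@snpsPerChrom)))
      return("selected loci must be a subset of simulated SNPs")
    sCols <- grep("^s_", names(object@selected), value = TRUE)
    if (length(sCols) != object@nDerived)
      return("one s_<pop> column per derived population is required")
    if (any(abs(as.matrix(object@selected[sCols])) >= 2))
      return("|true s| must be < 2")
  }
  TRUE
})
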