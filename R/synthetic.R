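#' Construct a synthetic metapopulation design
#'
#' Describes a simulated one-source, m-introduction study emulating a
#' replicated introduction experiment: a large source population supplies
#' founders to m derived populations which then drift (and optionally respond
#' to selection) for tau generations under per-generation census sizes, after
#' which a finite sample of diploids is genotyped from every population.
#'
#' Defaults describe the study conditions the package targets: four derived
#' populations and the source, 20 diploid samples each, seven generations,
#' founder spectrum from an Ne = 1000 source, small founding censuses growing
#' with fluctuation into the low thousands, 2% missing genotype calls.
#'
#' @param nDerived number of derived populations (default 4).
#' @param samplesPerPop diploids sampled per population (default 20).
#' @param snpsPerChrom integer vector of SNPs per chromosome
#'   (default four chromosomes of 2500).
#' @param bpPerSnp mean SNP spacing in bp (default 750).
#' @param founderNe effective size shaping the founder spectrum
#'   (default 1000).
#' @param census list of [CensusTrajectory] per derived population; `NULL`
#'   uses the default fluctuating trajectories (tau = 7).
#' @param selectedSnps integer global SNP indices under selection (default
#'   none).
#' @param selectedS selection coefficient magnitude(s) at those SNPs.
#' @param pattern sign pattern across derived populations (+1 parallel /
#'   -1 antiparallel), recycled to `nDerived`; default all +1.
#' @param selectedFounderFreq founder frequency pinned at selected loci
#'   (recycled; default 0.25, moderate standing variation); `numeric(0)`
#'   draws them from the spectrum instead.
#' @param missingness per-call missing probability (default 0.02).
#' @return a [SyntheticDesign].
#' @export
syntheticDesign <- function(nDerived = 4L, samplesPerPop = 20L,
                            snpsPerChrom = rep(2500L, 4L), bpPerSnp = 750L,
                            founderNe = 1000L, census = NULL,
                            selectedSnps = integer(), selectedS = 0.8,
                            pattern = 1, selectedFounderFreq = 0.25,
                            missingness = 0.02) {
  nDerived <- as.integer(nDerived)
  if (is.null(census)) {
    base <- c(150L, 400L, 900L, 700L, 1400L, 2200L, 1800L)
    mult <- rep_len(c(1, 0.8, 1.2, 0.9), nDerived)
    census <- lapply(seq_len(nDerived), function(i)
      CensusTrajectory(paste0("P", i), as.integer(round(base * mult[i]))))
  }
  pattern <- rep_len(sign(pattern), nDerived)
  selected <- if (length(selectedSnps)) {
    sMat <- outer(rep_len(selectedS, length(selectedSnps)), pattern)
    colnames(sMat) <- paste0("s_", vapply(census, function(cc) cc@population,
                                          character(1)))
    data.frame(snp = as.integer(selectedSnps), sMat)
  } else data.frame(snp = integer())
  new("SyntheticDesign", nDerived = nDerived,
      samplesPerPop = as.integer(samplesPerPop),
      snpsPerChrom = as.integer(snpsPerChrom),
      bpPerSnp = as.integer(bpPerSnp), founderNe = as.integer(founderNe),
      census = census, selected = selected,
      selectedFounderFreq = as.numeric(selectedFounderFreq),
      missingness = as.numeric(missingness))
}

setMethod("show", "SyntheticDesign", function(object) {
  cat("SyntheticDesign:", object@nDerived, "derived populations x",
      object@samplesPerPop, "samples;", sum(object@snpsPerChrom), "SNPs on",
      length(object@snpsPerChrom), "chromosome(s); tau =",
      generations(object@census[[1L]]), "\n")
  if (nrow(object@selected))
    cat("  selected loci:", nrow(object@selected), "\n")
})

#' Generate a synthetic dataset with its truth table
#'
#' Draws founder frequencies from the neutral folded spectrum, samples source
#' genotypes binomially from them, evolves every derived population forward
#' through its census trajectory with the Wright-Fisher kernel (applying the
#' deterministic diploid-additive selection update at selected loci before
#' each binomial draw), samples derived genotypes binomially from the final
#' frequencies, and masks genotypes at the design's missingness rate.
#' Deterministic under `seed`.
#'
#' @param design a [SyntheticDesign].
#' @param seed integer seed.
#' @return a list: `geno` ([GenotypeData] for source + derived samples),
#'   `registry` ([SampleRegistry], source labelled `"SRC"`), `census`,
#'   `truth` (`DataFrame` of selected loci: coordinates, true s per
#'   population), `founderFreqs`, and `finalFreqs` (true generation-tau
#'   frequencies, SNPs x derived populations).
#' @export
generateSynthetic <- function(design, seed) {
  set.seed(as.integer(seed))
  nSnp <- sum(design@snpsPerChrom)
  pops <- vapply(design@census, function(cc) cc@population, character(1))
  founder <- sampleFounderFrequencies(nSnp, ne = design@founderNe)
  if (nrow(design@selected) && length(design@selectedFounderFreq))
    founder[design@selected$snp] <- rep_len(design@selectedFounderFreq,
                                            nrow(design@selected))
  if (nrow(design@selected) &&
      any(founder[design@selected$snp] %in% c(0, 1)))
    stop("selected locus with founder frequency 0 or 1 is undetectable")
  chrom <- rep(paste0("chr", seq_along(design@snpsPerChrom)),
               design@snpsPerChrom)
  pos <- unlist(lapply(design@snpsPerChrom, function(k)
    sort(sample.int(k * design@bpPerSnp, k))), use.names = FALSE)
  alleles <- c("A", "C", "G", "T")
  ref <- sample(alleles, nSnp, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(alleles, r), 1L),
                character(1), USE.NAMES = FALSE)

  sampleGeno <- function(p, prefix) {
    g <- stats::rbinom(nSnp * design@samplesPerPop, 2L,
                       rep(p, design@samplesPerPop))
    dim(g) <- c(nSnp, design@samplesPerPop)
    colnames(g) <- sprintf("%s_%02d", prefix, seq_len(design@samplesPerPop))
    g
  }
  gt <- sampleGeno(founder, "SRC")
  finalFreqs <- matrix(NA_real_, nSnp, length(pops),
                       dimnames = list(NULL, pops))
  sCols <- paste0("s_", pops)
  for (j in seq_along(pops)) {
    sVec <- numeric(nSnp)
    if (nrow(design@selected))
      sVec[design@selected$snp] <- design@selected[[sCols[j]]]
    batch <- simulatePopulation(founder, design@census[[j]],
                                replicates = 1L, s = sVec)
    finalFreqs[, j] <- finalFreqs(batch)[1L, ]
    gt <- cbind(gt, sampleGeno(finalFreqs[, j], pops[j]))
  }
  if (design@missingness > 0) {
    miss <- stats::runif(length(gt)) < design@missingness
    gt[miss] <- NA_integer_
  }
  storage.mode(gt) <- "integer"
  registry <- SampleRegistry(colnames(gt),
                             rep(c("SRC", pops),
                                 each = design@samplesPerPop),
                             sourcePop = "SRC")
  truth <- if (nrow(design@selected))
    DataFrame(chrom = chrom[design@selected$snp],
              pos = pos[design@selected$snp],
              snp = design@selected$snp,
              founderFreq = founder[design@selected$snp],
              DataFrame(design@selected[sCols]))
  else DataFrame()
  list(geno = GenotypeData(gt, chrom, pos, ref, alt), registry = registry,
       census = design@census, truth = truth, founderFreqs = founder,
       finalFreqs = finalFreqs, seed = as.integer(seed))
}

#' Write a registry as a two-column popmap TSV
#'
#' @param registry a [SampleRegistry].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePopmap <- function(registry, path) {
  utils::write.table(data.frame(sampleIds(registry), popLabels(registry)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Write census trajectories as a (population, generation, N) TSV
#'
#' @param census list of [CensusTrajectory].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeCensus <- function(census, path) {
  tab <- do.call(rbind, lapply(census, function(cc)
    data.frame(population = cc@population,
               generation = seq_along(cc@sizes), N = cc@sizes)))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read census trajectories from a (population, generation, N) TSV
#'
#' @param path input path.
#' @return named list of [CensusTrajectory].
#' @export
readCensus <- function(path) {
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  lapply(split(tab, tab$population), function(d)
    CensusTrajectory(d$population[1L], d$N[order(d$generation)]))
}
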