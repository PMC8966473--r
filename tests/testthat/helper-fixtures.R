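suppressPackageStartupMessages({
  library(SummarizedExperiment)
  library(S4Vectors)
})

# frequency table built directly from a matrix (columns = populations),
# bypassing genotype IO, for unit tests of downstream modules
makeFreqTable <- function(freq, sourcePop, chrom = "chr1",
                          pos = seq_len(nrow(freq)) * 100L,
                          nChr = 40L, popSizes = NULL) {
  freq <- as.matrix(freq)
  gr <- GenomicRanges::GRanges(rep_len(chrom, nrow(freq)),
                               IRanges::IRanges(pos, width = 1L),
                               REF = "A", ALT = "C",
                               polarized = "ALT")
  if (is.null(popSizes))
    popSizes <- setNames(rep(20L, ncol(freq)), colnames(freq))
  new("AlleleFreqTable",
      SummarizedExperiment(
        assays = list(freq = freq,
                      nChr = matrix(nChr, nrow(freq), ncol(freq),
                                    dimnames = dimnames(freq))),
        rowRanges = gr,
        metadata = list(sourcePop = sourcePop, minCalledFraction = 0.5,
                        popSizes = popSizes)))
}

# raw change-vector window from a bare matrix
makeWindow <- function(X, normalized = FALSE, chrom = "chr1") {
  if (is.null(rownames(X))) rownames(X) <- paste0("P", seq_len(nrow(X)))
  new("DeltaAFWindow", chrom = chrom, startBp = 1L,
      endBp = ncol(X) * 100L, snpIdx = seq_len(ncol(X)), X = X,
      normalized = normalized, usable = TRUE)
}

# random unit-row window: m change vectors of n SNPs
randomUnitWindow <- function(m = 4L, n = 200L) {
  X <- matrix(runif(m * n, -0.5, 0.5), m, n)
  X <- X / sqrt(rowSums(X^2))
  makeWindow(X, normalized = TRUE)
}

# small genotype fixture: nPop populations of nSamp diploids drawn from
# per-population frequency vectors (list of length nPop)
makeGenotypes <- function(freqList, nSamp = 10L, chrom = NULL,
                          missing = 0) {
  nSnp <- length(freqList[[1L]])
  gt <- do.call(cbind, lapply(seq_along(freqList), function(j) {
    g <- rbinom(nSnp * nSamp, 2L, rep(freqList[[j]], nSamp))
    dim(g) <- c(nSnp, nSamp)
    colnames(g) <- sprintf("%s_%02d", names(freqList)[j], seq_len(nSamp))
    g
  }))
  if (missing > 0) gt[runif(length(gt)) < missing] <- NA_integer_
  storage.mode(gt) <- "integer"
  if (is.null(chrom)) chrom <- rep("chr1", nSnp)
  geno <- GenotypeData(gt, chrom, seq_len(nSnp) * 50L,
                       rep("A", nSnp), rep("G", nSnp))
  registry <- SampleRegistry(colnames(gt),
                             rep(names(freqList), each = nSamp),
                             sourcePop = names(freqList)[1L])
  list(geno = geno, registry = registry, gt = gt)
}
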