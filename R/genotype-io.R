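#' Construct a GenotypeData object
#'
#' @param gt integer matrix of alternate-allele dosages (sites x samples;
#'   0/1/2 or `NA`), with sample ids as column names.
#' @param chrom,pos per-site chromosome and 1-based position.
#' @param ref,alt per-site reference and alternate alleles.
#' @return a [GenotypeData].
#' @export
GenotypeData <- function(gt, chrom, pos, ref, alt) {
  gr <- GRanges(chrom, IRanges(start = as.integer(pos), width = 1L),
                REF = as.character(ref), ALT = as.character(alt))
  new("GenotypeData",
      SummarizedExperiment(assays = list(GT = gt), rowRanges = gr))
}

setMethod("show", "GenotypeData", function(object) {
  cat("GenotypeData:", nrow(object), "biallelic SNPs x", ncol(object),
      "samples on", length(unique(as.character(seqnames(object)))),
      "chromosome(s)\n")
})

GT_CODES <- c("0/0" = 0L, "0|0" = 0L, "0/1" = 1L, "1/0" = 1L, "0|1" = 1L,
              "1|0" = 1L, "1/1" = 2L, "1|1" = 2L)

#' Read biallelic SNP genotypes from a VCF
#'
#' Parses a multi-sample VCF (plain or gzipped; GT field required), keeping
#' only biallelic SNPs. Multiallelic records and indels are skipped with a
#' message reporting the count.
#'
#' @param path path to the VCF.
#' @param region optional region filter, `"chrom"` or `"chrom:start-end"`
#'   (1-based, inclusive).
#' @param registry optional [SampleRegistry]; when supplied, every sample in
#'   the file must be registered.
#' @return a [GenotypeData].
#' @export
readVariants <- function(path, region = NULL, registry = NULL) {
  if (!file.exists(path)) stop("variant file not found: ", path)
  vcf <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                  error = function(e) stop("unreadable variant file: ", path,
                                           " (", conditionMessage(e), ")"))
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L,
                                       dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  snp <- !grepl(",", alt, fixed = TRUE) & nchar(ref) == 1L &
    nchar(alt) == 1L & alt != "." & ref %in% c("A", "C", "G", "T") &
    alt %in% c("A", "C", "G", "T")
  if (any(!snp))
    message(sum(!snp), " non-biallelic-SNP record(s) skipped")
  gtChr <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gtChr)) stop("VCF has no GT genotype field")
  gt <- matrix(GT_CODES[gtChr], nrow = nrow(gtChr),
               dimnames = list(NULL, colnames(gtChr)))
  chrom <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  keep <- which(snp)
  if (!is.null(region)) {
    parts <- regmatches(region,
                        regexec("^([^:]+)(?::([0-9]+)-([0-9]+))?$", region))[[1]]
    if (!length(parts)) stop("malformed region: ", region)
    inr <- chrom == parts[2]
    if (nzchar(parts[3]))
      inr <- inr & pos >= as.integer(parts[3]) & pos <= as.integer(parts[4])
    keep <- intersect(keep, which(inr))
  }
  if (!is.null(registry)) {
    unknown <- setdiff(colnames(gt), sampleIds(registry))
    if (length(unknown))
      stop("sample in variant file absent from registry: ", unknown[1L])
  }
  GenotypeData(gt[keep, , drop = FALSE], chrom[keep], pos[keep],
               ref[keep], alt[keep])
}

#' Write genotypes to a plain-text VCF (v4.2)
#'
#' @param geno a [GenotypeData].
#' @param path output path; written uncompressed.
#' @return `path`, invisibly.
#' @export
writeVcf <- function(geno, path) {
  gr <- rowRanges(geno)
  chrom <- as.character(seqnames(gr))
  gt <- assay(geno, "GT")
  lens <- vapply(split(end(gr), chrom), max, numeric(1))
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", names(lens),
                   as.integer(lens) + 1000L),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", colnames(gt)), collapse = "\t"))
  codes <- c("0/0", "0/1", "1/1")
  body <- matrix("./.", nrow = nrow(gt), ncol = ncol(gt))
  ok <- !is.na(gt)
  body[ok] <- codes[gt[ok] + 1L]
  lines <- paste(chrom, start(gr), ".", rowData(geno)$REF, rowData(geno)$ALT,
                 ".", "PASS", ".", "GT",
                 apply(body, 1L, paste, collapse = "\t"), sep = "\t")
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write: ", path))
  on.exit(close(con))
  writeLines(c(hdr, lines), con)
  invisible(path)
}

# Per-population alt-allele copies and non-missing chromosome counts.
# Returns list(alt = sites x pops, nChr = sites x pops).
popCounts <- function(gt, popIdx) {
  g0 <- gt
  g0[is.na(g0)] <- 0L
  called <- !is.na(gt)
  alt <- vapply(popIdx, function(i) .rowSums(g0[, i, drop = FALSE],
                                             nrow(gt), length(i)),
                numeric(nrow(gt)))
  nChr <- vapply(popIdx, function(i) 2 * .rowSums(called[, i, drop = FALSE],
                                                  nrow(gt), length(i)),
                 numeric(nrow(gt)))
  if (nrow(gt) == 1L) {
    alt <- matrix(alt, nrow = 1L, dimnames = list(NULL, names(popIdx)))
    nChr <- matrix(nChr, nrow = 1L, dimnames = list(NULL, names(popIdx)))
  }
  list(alt = alt, nChr = nChr)
}

#' Compute polarized per-population allele frequencies
#'
#' Per-population frequencies are alternate-allele copies over non-missing
#' chromosomes. Sites where any population's called fraction falls below
#' `minCalledFraction`, and sites monomorphic across all populations, are
#' dropped. Remaining sites are polarized to the source population's minor
#' allele (ties at 0.5 keep the alternate allele).
#'
#' @param geno a [GenotypeData].
#' @param registry a [SampleRegistry]; all registered samples must be present.
#' @param minCalledFraction minimum per-population fraction of called
#'   chromosomes, in (0, 1].
#' @return an [AlleleFreqTable].
#' @export
computeFrequencies <- function(geno, registry, minCalledFraction = 0.5) {
  stopifnot(minCalledFraction > 0, minCalledFraction <= 1)
  gt <- assay(geno, "GT")
  popIdx <- popIndexList(registry, colnames(gt))
  cnt <- popCounts(gt, popIdx)
  maxChr <- 2 * vapply(popIdx, length, integer(1))
  callFrac <- sweep(cnt$nChr, 2L, maxChr, "/")
  keep <- rowSums(callFrac < minCalledFraction) == 0L
  freq <- cnt$alt / cnt$nChr
  if (any(keep & !is.finite(rowSums(freq))))
    stop("internal error: retained site with zero called chromosomes")
  mono <- rowSums(freq == 0) == ncol(freq) | rowSums(freq == 1) == ncol(freq)
  keep <- which(keep & !mono)
  freq <- freq[keep, , drop = FALSE]
  nChr <- cnt$nChr[keep, , drop = FALSE]
  src <- sourcePopulation(registry)
  flip <- freq[, src] > 0.5
  freq[flip, ] <- 1 - freq[flip, , drop = FALSE]
  gr <- rowRanges(geno)[keep]
  S4Vectors::mcols(gr)$polarized <- ifelse(flip, "REF", "ALT")
  new("AlleleFreqTable",
      SummarizedExperiment(assays = list(freq = freq, nChr = nChr),
                           rowRanges = gr,
                           metadata = list(
                             sourcePop = src,
                             minCalledFraction = minCalledFraction,
                             popSizes = vapply(popIdx, length,
                                               integer(1)))))
}

#' @rdname AlleleFreqTable
#' @param x an [AlleleFreqTable].
#' @export
setMethod("freqMatrix", "AlleleFreqTable", function(x) assay(x, "freq"))

#' @rdname AlleleFreqTable
#' @export
setMethod("sourceFreqs", "AlleleFreqTable",
          function(x) assay(x, "freq")[, metadata(x)$sourcePop])

setMethod("show", "AlleleFreqTable", function(object) {
  cat("AlleleFreqTable:", nrow(object), "polarized SNPs x", ncol(object),
      "populations (source:", metadata(object)$sourcePop, ")\n")
})

#' Count sites where the source-minor allele is fixed in a derived population
#'
#' @param freqs an [AlleleFreqTable].
#' @param derived population label.
#' @return integer count of sites with polarized-allele frequency exactly 1.
#' @export
countFixedSourceMinor <- function(freqs, derived) {
  f <- freqMatrix(freqs)
  if (!derived %in% colnames(f)) stop("unknown population: ", derived)
  sum(f[, derived] == 1)
}

#' Mean absolute allele-frequency change in fixed-width windows
#'
#' Tiles each chromosome with non-overlapping half-open windows
#' `[start, start + windowBp)` from position 1 and reports the mean of
#' |freq(derived) - freq(source)| over the SNPs in each window. Windows with
#' no SNPs (within the span of observed positions) get `NA`.
#'
#' @param freqs an [AlleleFreqTable].
#' @param derived derived population label.
#' @param windowBp window width in base pairs (default 75000).
#' @return a `DataFrame` with chrom, start, end (half-open), nSnps,
#'   meanAbsDeltaAF.
#' @export
windowedDeltaAF <- function(freqs, derived, windowBp = 75000L) {
  stopifnot(windowBp > 0)
  f <- freqMatrix(freqs)
  if (!derived %in% colnames(f)) stop("unknown population: ", derived)
  dAF <- abs(f[, derived] - sourceFreqs(freqs))
  chrom <- as.character(seqnames(freqs))
  pos <- start(rowRanges(freqs))
  res <- lapply(unique(chrom), function(ch) {
    sel <- chrom == ch
    win <- (pos[sel] - 1L) %/% windowBp
    nWin <- max(win) + 1L
    cnt <- tabulate(win + 1L, nbins = nWin)
    s <- vapply(seq_len(nWin) - 1L,
                function(w) mean(dAF[sel][win == w]), numeric(1))
    s[cnt == 0L] <- NA_real_
    DataFrame(chrom = ch, start = seq_len(nWin) * windowBp - windowBp + 1L,
              end = seq_len(nWin) * windowBp + 1L, nSnps = cnt,
              meanAbsDeltaAF = s)
  })
  do.call(rbind, res)
}
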