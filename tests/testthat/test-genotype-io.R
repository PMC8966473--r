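test_that("popmap reading builds a valid registry and rejects bad input", {
  path <- withr::local_tempfile(fileext = ".tsv")
  # five-population design, 94 samples total (20+20+18+18+18)
  pops <- rep(c("GHP", "ILL", "IUL", "IC", "IT"), c(20, 20, 18, 18, 18))
  writeLines(paste(sprintf("s%03d", seq_along(pops)), pops, sep = "\t"),
             path)
  reg <- readPopmap(path, sourcePop = "GHP")
  expect_s4_class(reg, "SampleRegistry")
  expect_length(reg, 94L)
  expect_setequal(unique(popLabels(reg)), c("GHP", "ILL", "IUL", "IC", "IT"))
  expect_identical(sourcePopulation(reg), "GHP")
  expect_setequal(derivedPopulations(reg), c("ILL", "IUL", "IC", "IT"))

  single <- withr::local_tempfile(fileext = ".tsv")
  writeLines("only\tP1", single)
  expect_length(readPopmap(single, "P1"), 1L)

  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("a\tP1", "a\tP2"), dup)
  expect_error(readPopmap(dup, "P1"), "duplicate sample")
  expect_error(readPopmap(path, "NOPE"), "not present")
})

test_that("VCF writing and reading round-trips genotypes exactly", {
  set.seed(101)
  fix <- makeGenotypes(list(SRC = runif(30, 0.05, 0.95),
                            P1 = runif(30, 0.05, 0.95)), nSamp = 6L,
                       missing = 0.1)
  path <- withr::local_tempfile(fileext = ".vcf")
  writeVcf(fix$geno, path)
  back <- readVariants(path)
  expect_identical(unname(assay(back, "GT")), unname(fix$gt))
  expect_identical(colnames(back), colnames(fix$gt))
  expect_identical(start(rowRanges(back)), start(rowRanges(fix$geno)))
  expect_identical(rowData(back)$REF, rowData(fix$geno)$REF)
})

test_that("multiallelic and indel records are skipped with a count", {
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2")
  rec <- function(pos, ref, alt)
    sprintf("chr1\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT\t0/1\t1/1", pos, ref, alt)
  lines <- c(hdr, vapply(1:8, function(i) rec(i * 10L, "A", "G"),
                         character(1)),
             rec(90L, "A", "G,T"),   # triallelic
             rec(100L, "AT", "A"))   # indel
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(lines, path)
  expect_message(v <- readVariants(path), "2 non-biallelic-SNP")
  expect_identical(nrow(v), 8L)
})

test_that("region queries subset to the requested interval", {
  set.seed(7)
  fix <- makeGenotypes(list(SRC = runif(20, 0.2, 0.8),
                            P1 = runif(20, 0.2, 0.8)), nSamp = 4L,
                       chrom = rep(c("chr1", "chr2"), each = 10L))
  path <- withr::local_tempfile(fileext = ".vcf")
  writeVcf(fix$geno, path)
  one <- readVariants(path, region = "chr2")
  expect_identical(nrow(one), 10L)
  expect_true(all(seqnames(one) == "chr2"))
  sub <- readVariants(path, region = "chr1:1-250")
  expect_true(all(start(rowRanges(sub)) <= 250L))
  expect_identical(nrow(sub), 5L)
})

test_that("a file sample missing from a supplied registry is fatal", {
  set.seed(3)
  fix <- makeGenotypes(list(SRC = runif(5, 0.3, 0.7),
                            P1 = runif(5, 0.3, 0.7)), nSamp = 3L)
  path <- withr::local_tempfile(fileext = ".vcf")
  writeVcf(fix$geno, path)
  small <- SampleRegistry(sampleIds(fix$registry)[-1L],
                          popLabels(fix$registry)[-1L], "SRC")
  expect_error(readVariants(path, registry = small), "SRC_01")
  expect_silent(suppressMessages(readVariants(path,
                                              registry = fix$registry)))
})

test_that("frequencies are alt copies over called chromosomes", {
  gt <- matrix(c(0L, 1L,   # SRC: 1 alt copy / 4 chromosomes
                 2L, 1L),  # P1
               nrow = 1)
  colnames(gt) <- c("a", "b", "c", "d")
  geno <- GenotypeData(gt, "chr1", 100L, "A", "G")
  reg <- SampleRegistry(c("a", "b", "c", "d"),
                        c("SRC", "SRC", "P1", "P1"), "SRC")
  f <- computeFrequencies(geno, reg)
  expect_equal(unname(freqMatrix(f)[1, "SRC"]), 0.25)
  expect_equal(unname(freqMatrix(f)[1, "P1"]), 0.75)
})

test_that("polarization reports the source minor allele, ties keep ALT", {
  # site 1: source alt freq 0.8 -> flip to REF, report 0.2
  # site 2: source alt freq 0.5 -> tie, keep ALT
  gt <- rbind(c(2L, 2L, 2L, 1L, 1L, 1L, 0L),
              c(1L, 1L, 1L, 1L, 1L, 2L, 0L))
  colnames(gt) <- letters[1:7]
  geno <- GenotypeData(gt, "chr1", c(10L, 20L), c("A", "A"), c("G", "G"))
  reg <- SampleRegistry(letters[1:7],
                        c(rep("SRC", 5L), "P1", "P1"), "SRC")
  f <- computeFrequencies(geno, reg)
  expect_equal(unname(freqMatrix(f)[1, "SRC"]), 0.2)
  expect_equal(unname(freqMatrix(f)[1, "P1"]), 0.75)
  expect_identical(rowData(f)$polarized, c("REF", "ALT"))
  expect_equal(unname(freqMatrix(f)[2, "SRC"]), 0.5)
  # polarization is idempotent: no retained source frequency exceeds 0.5,
  # so re-applying the flip rule would change nothing
  expect_true(all(sourceFreqs(f) <= 0.5))
})

test_that("frequencies with missing data match a per-site hand count", {
  set.seed(42)
  fix <- makeGenotypes(list(SRC = runif(50, 0.1, 0.9),
                            P1 = runif(50, 0.1, 0.9),
                            P2 = runif(50, 0.1, 0.9)),
                       nSamp = 20L, missing = 0.1)
  f <- computeFrequencies(fix$geno, fix$registry, minCalledFraction = 0.5)
  pos <- start(rowRanges(f))
  pops <- c("SRC", "P1", "P2")
  for (i in seq_along(pos)) {
    site <- fix$gt[pos[i] / 50L, ]
    for (pop in pops) {
      g <- site[grep(pop, names(site))]
      raw <- sum(g, na.rm = TRUE) / (2 * sum(!is.na(g)))
      # undo polarization for comparison
      obs <- freqMatrix(f)[i, pop]
      if (rowData(f)$polarized[i] == "REF") obs <- 1 - obs
      expect_equal(unname(obs), raw)
    }
  }
})

test_that("low call-rate sites and monomorphic sites are dropped", {
  gt <- rbind(c(NA, NA, 1L, 1L),   # SRC all-missing: dropped
              c(0L, 0L, 0L, 0L),   # monomorphic everywhere: dropped
              c(2L, 2L, 2L, 2L),   # monomorphic everywhere: dropped
              c(0L, 1L, 2L, 1L))   # retained
  colnames(gt) <- letters[1:4]
  geno <- GenotypeData(gt, "chr1", c(1L, 2L, 3L, 4L) * 10L,
                       rep("A", 4), rep("G", 4))
  reg <- SampleRegistry(letters[1:4], c("SRC", "SRC", "P1", "P1"), "SRC")
  f <- computeFrequencies(geno, reg, minCalledFraction = 0.5)
  expect_identical(nrow(f), 1L)
  expect_identical(start(rowRanges(f)), 40L)
})

test_that("fixed source-minor counting matches an independent scan", {
  set.seed(9)
  freq <- cbind(SRC = runif(100, 0.05, 0.45),
                P1 = c(rep(1, 3), runif(97, 0.1, 0.9)),
                P2 = runif(100, 0.1, 0.9))
  f <- makeFreqTable(freq, "SRC")
  expect_identical(countFixedSourceMinor(f, "P1"), 3L)
  # derived population identical to the source: nothing fixed
  f2 <- makeFreqTable(cbind(SRC = freq[, "SRC"], P1 = freq[, "SRC"]), "SRC")
  expect_identical(countFixedSourceMinor(f2, "P1"), 0L)
  # brute-force oracle on a drifted fixture
  set.seed(10)
  drift <- pmin(1, pmax(0, freq[, "SRC"] + rnorm(100, 0, 0.4)))
  f3 <- makeFreqTable(cbind(SRC = freq[, "SRC"], P1 = drift), "SRC")
  oracle <- 0L
  for (i in 1:100) if (drift[i] == 1) oracle <- oracle + 1L
  expect_identical(countFixedSourceMinor(f3, "P1"), oracle)
  expect_error(countFixedSourceMinor(f, "P9"), "unknown population")
})

test_that("windowed mean |dAF| matches direct averaging and tiles all SNPs", {
  f1 <- makeFreqTable(cbind(SRC = 0.2, P1 = 0.5), "SRC", pos = 10L)
  w1 <- windowedDeltaAF(f1, "P1", windowBp = 75000L)
  expect_equal(w1$meanAbsDeltaAF, 0.3)
  expect_identical(w1$nSnps, 1L)

  f2 <- makeFreqTable(cbind(SRC = c(0.2, 0.4), P1 = c(0.3, 0.1)), "SRC",
                      pos = c(10L, 20L))
  expect_equal(windowedDeltaAF(f2, "P1")$meanAbsDeltaAF, 0.2)

  set.seed(11)
  n <- 300L
  pos <- sort(sample.int(40000L, n))
  freq <- cbind(SRC = runif(n, 0.05, 0.5), P1 = runif(n))
  f3 <- makeFreqTable(freq, "SRC", pos = pos)
  w3 <- windowedDeltaAF(f3, "P1", windowBp = 5000L)
  oracle <- tapply(abs(freq[, "P1"] - freq[, "SRC"]),
                   (pos - 1L) %/% 5000L, mean)
  got <- w3$meanAbsDeltaAF[w3$nSnps > 0L]
  expect_equal(unname(got),
               as.vector(oracle[order(as.integer(names(oracle)))]))
  expect_identical(sum(w3$nSnps), n)
  # half-open tiling from position 1
  expect_identical(w3$start[1L], 1L)
  expect_identical(w3$end - w3$start, rep(5000L, nrow(w3)))
  expect_true(all(is.na(w3$meanAbsDeltaAF[w3$nSnps == 0L])))
  expect_true(all(w3$meanAbsDeltaAF >= 0 & w3$meanAbsDeltaAF <= 1,
                  na.rm = TRUE))
})
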