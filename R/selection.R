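#' Standardized selection coefficient from temporal allele frequencies
#'
#' The per-generation additive selection intensity that would
#' deterministically produce the observed logit allele-frequency change over
#' tau generations under a diploid single-locus model:
#' s = (2 / tau) * ln(p_tau q_0 / (p_0 q_tau)), with q = 1 - p. Final
#' frequencies of exactly 0 or 1 (lost or fixed, where the log-odds diverge)
#' are replaced by `clamp` and `1 - clamp`.
#'
#' @param p0 founding frequency (or vector), strictly inside (0, 1).
#' @param pTau frequency at sampling, in [0, 1]; vectorized.
#' @param tau generations between founding and sampling.
#' @param clamp frequency floor in (0, 0.5) standing in for an unobserved
#'   frequency below the detection limit.
#' @return s, same length as the longer of `p0`/`pTau`.
#' @examples
#' standardizedS(0.1, 0.5, tau = 7, clamp = 0.01)  # (2/7) * log(9)
#' @export
standardizedS <- function(p0, pTau, tau, clamp = 0.01) {
  stopifnot(tau > 0, clamp > 0, clamp < 0.5)
  if (any(p0 <= 0 | p0 >= 1))
    stop("p0 must lie strictly inside (0, 1): change from a fixed founder ",
         "is undefined under this model")
  pTau <- pmin(pmax(pTau, clamp), 1 - clamp)
  (2 / tau) * (log(pTau / (1 - pTau)) - log(p0 / (1 - p0)))
}

#' Per-population and summed selection coefficients for observed data
#'
#' Computes the standardized selection coefficient of every derived
#' population at every SNP, taking the source sample frequency as the
#' founding frequency, and sums the signed values within SNPs across
#' populations: the sum is maximized by change that is large and
#' co-directional. Because all frequencies are polarized to the source minor
#' allele, signs are comparable across populations.
#'
#' Sites where the polarized allele is absent from the source sample
#' (frequency 0, polymorphic elsewhere) have their founding frequency raised
#' to the source population's clamp floor, mirroring the clamping of fixed
#' final frequencies.
#'
#' @param freqs an [AlleleFreqTable].
#' @param tau generations between founding and sampling: scalar or named
#'   vector (one per derived population).
#' @param clamp frequency floor; `NULL` (default) uses the per-population
#'   rule 1 / (2 nChr + 1) with nChr the population's sampled chromosomes.
#' @return a `DataFrame` with chrom, pos, per-population `s_<pop>` columns
#'   and `summed`; clamp values used are in `metadata()$clamp`.
#' @export
selectionCoefficients <- function(freqs, tau = 7, clamp = NULL) {
  f <- freqMatrix(freqs)
  src <- metadata(freqs)$sourcePop
  derived <- setdiff(colnames(f), src)
  popSizes <- metadata(freqs)$popSizes
  clampOf <- function(pop) {
    if (!is.null(clamp)) return(clamp)
    1 / (2 * (2 * popSizes[[pop]]) + 1)
  }
  tauOf <- if (length(tau) == 1L) stats::setNames(rep(tau, length(derived)),
                                                  derived) else tau[derived]
  p0 <- pmax(f[, src], clampOf(src))
  sMat <- vapply(derived, function(pop)
    standardizedS(p0, f[, pop], tauOf[[pop]], clampOf(pop)),
    numeric(nrow(f)))
  if (nrow(f) == 1L)
    sMat <- matrix(sMat, nrow = 1L, dimnames = list(NULL, derived))
  colnames(sMat) <- paste0("s_", derived)
  out <- DataFrame(chrom = as.character(seqnames(freqs)),
                   pos = start(rowRanges(freqs)), DataFrame(sMat),
                   summed = rowSums(sMat))
  metadata(out)$clamp <- vapply(c(src, derived), clampOf, numeric(1))
  metadata(out)$tau <- tauOf
  out
}

#' Sum selection coefficients within SNPs across populations
#'
#' @param sMatrix numeric matrix (SNPs x populations) of signed selection
#'   coefficients, all computed on the same polarized allele; or a list of
#'   equal-length per-population vectors.
#' @return per-SNP arithmetic sum.
#' @export
summedS <- function(sMatrix) {
  if (is.list(sMatrix)) {
    n <- lengths(sMatrix)
    if (length(unique(n)) != 1L)
      stop("per-population SNP sets differ in size")
    sMatrix <- do.call(cbind, sMatrix)
  }
  rowSums(sMatrix)
}

#' Neutral quantile thresholds for summed selection coefficients
#'
#' Computes, for every simulated replicate and SNP, the standardized
#' selection coefficient of each population from its neutral drift batch,
#' sums across populations (pairing replicate r of every population: the
#' populations were founded independently, so any fixed pairing is
#' exchangeable), pools all summed values, and returns the requested
#' quantiles of the pooled |summed s| (two-sided) or of the pooled signed
#' sums' upper tail (one-sided).
#'
#' When the observed selection coefficients are computed from finite
#' population samples, their sampling noise must be carried into the null:
#' `sampleChromosomes` resamples each simulated final frequency binomially at
#' the study's per-population chromosome counts, and `sourceChromosomes`
#' replaces the true founding frequency with an independent per-replicate
#' binomial source-sample frequency shared across populations (matching the
#' observed analysis, where one source sample supplies p0 for every
#' population).
#'
#' @param batches named list of [SimulationBatch], one per derived
#'   population, simulated with identical founding frequencies and replicate
#'   counts.
#' @param tau scalar or named per-population generations.
#' @param clamp scalar frequency floor, or named per-population vector
#'   (include the entry `"source"` when `sourceChromosomes` is used).
#' @param probs quantile levels (default 0.99, 0.999, 0.9999).
#' @param twoSided take quantiles of |summed s| (default `TRUE`).
#' @param sampleChromosomes optional named per-population chromosome counts
#'   for binomial resampling of final frequencies.
#' @param sourceChromosomes optional source-sample chromosome count.
#' @param seed optional seed for the resampling step.
#' @return a [SummedSNull].
#' @export
neutralQuantiles <- function(batches, tau = 7, clamp = 0.01,
                             probs = c(0.99, 0.999, 0.9999),
                             twoSided = TRUE, sampleChromosomes = NULL,
                             sourceChromosomes = NULL, seed = NULL) {
  pops <- names(batches)
  R <- unique(vapply(batches, function(b) nrow(b@final), integer(1)))
  if (length(R) != 1L)
    stop("replicate counts differ across population batches")
  founding <- batches[[1L]]@founding
  for (b in batches)
    if (!isTRUE(all.equal(b@founding, founding)))
      stop("founding frequencies differ across population batches")
  if (!is.null(seed)) set.seed(as.integer(seed))
  nSnp <- length(founding)
  tauOf <- if (length(tau) == 1L) stats::setNames(rep(tau, length(pops)),
                                                  pops) else tau[pops]
  clampOf <- function(pop) if (length(clamp) == 1L) clamp else clamp[[pop]]
  p0 <- matrix(founding, nrow = R, ncol = nSnp, byrow = TRUE)
  ascertain <- !is.null(sampleChromosomes) || !is.null(sourceChromosomes)
  if (!is.null(sourceChromosomes)) {
    p0 <- stats::rbinom(R * nSnp, sourceChromosomes, p0) / sourceChromosomes
    dim(p0) <- c(R, nSnp)
  }
  allZero <- if (ascertain) p0 == 0 else NULL
  allOne <- if (ascertain) p0 == 1 else NULL
  if (!is.null(sourceChromosomes)) {
    cl <- clampOf("source")
    p0 <- pmin(pmax(p0, cl), 1 - cl)
  }
  total <- 0
  for (pop in pops) {
    pT <- batches[[pop]]@final
    if (!is.null(sampleChromosomes)) {
      nc <- sampleChromosomes[[pop]]
      pT <- stats::rbinom(R * nSnp, nc, pT) / nc
      dim(pT) <- c(R, nSnp)
    }
    if (ascertain) {
      allZero <- allZero & pT == 0
      allOne <- allOne & pT == 1
    }
    cl <- clampOf(pop)
    pT <- pmin(pmax(pT, cl), 1 - cl)
    total <- total + (2 / tauOf[[pop]]) *
      (log(pT / (1 - pT)) - log(p0 / (1 - p0)))
  }
  pooled <- if (twoSided) abs(as.numeric(total)) else as.numeric(total)
  if (ascertain) {
    # mirror the observed pipeline's ascertainment: a draw whose tracked
    # allele is absent or fixed in every pseudo-sample corresponds to a site
    # the monomorphic filter would have removed
    pooled <- pooled[!(as.logical(allZero) | as.logical(allOne))]
  }
  thr <- stats::quantile(pooled, probs, type = 1, names = FALSE)
  new("SummedSNull", thresholds = stats::setNames(thr, format(probs)),
      probs = probs, twoSided = twoSided,
      tau = unname(tauOf[1L]),
      clamp = if (length(clamp) == 1L) clamp else unname(clamp[1L]),
      nValues = length(pooled))
}

setMethod("show", "SummedSNull", function(object) {
  cat("SummedSNull (", if (object@twoSided) "two-sided" else "one-sided",
      ", ", object@nValues, " pooled values):\n", sep = "")
  print(signif(object@thresholds, 4))
})

#' Flag SNPs exceeding neutral summed-s thresholds
#'
#' Assigns each SNP the highest quantile tier whose threshold its summed
#' selection coefficient exceeds (|summed s| for a two-sided null); tiers are
#' nested by construction. Also reports per-chromosome observed versus
#' expected outlier counts at each tier (expected = tail fraction x SNPs on
#' the chromosome).
#'
#' @param observed `DataFrame` from [selectionCoefficients].
#' @param thresholds a [SummedSNull].
#' @return `observed` with a `tier` column ("none" or the tier's quantile);
#'   the per-chromosome summary is in `metadata()$chromSummary`.
#' @export
flagOutlierSnps <- function(observed, thresholds) {
  val <- if (thresholds@twoSided) abs(observed$summed) else observed$summed
  ord <- order(thresholds@probs)
  probs <- thresholds@probs[ord]
  thr <- thresholds@thresholds[ord]
  tier <- rep("none", length(val))
  for (i in seq_along(probs)) tier[val > thr[i]] <- format(probs[i])
  observed$tier <- tier
  chroms <- unique(observed$chrom)
  summ <- DataFrame(chrom = chroms,
                    nSnps = vapply(chroms, function(ch)
                      sum(observed$chrom == ch), integer(1)))
  for (i in seq_along(probs)) {
    nm <- format(probs[i])
    summ[[paste0("observed_", nm)]] <- vapply(chroms, function(ch)
      sum(val > thr[i] & observed$chrom == ch), integer(1))
    summ[[paste0("expected_", nm)]] <- (1 - probs[i]) * summ$nSnps
  }
  metadata(observed)$chromSummary <- summ
  metadata(observed)$thresholds <- thresholds@thresholds
  observed
}
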