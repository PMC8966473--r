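#' One permutation replicate of the eigenvalue null
#'
#' Draws a random window of exactly `snpsPerWindow` consecutive SNPs (uniform
#' random start in SNP-index space; windows crossing a chromosome boundary
#' are rejected and redrawn), shuffles all individual labels across the
#' pooled populations, refills groups of the original sizes (one
#' pseudo-source plus the derived-population group sizes), and recomputes
#' allele frequencies, the ΔAF matrix, row normalization and eigenvalues
#' exactly as in the observed analysis. A shuffle producing an all-zero
#' change vector is redrawn.
#'
#' Polarization is skipped: flipping a SNP's allele flips one column of X in
#' every row simultaneously, which leaves C = XX' unchanged.
#'
#' @param gt integer dosage matrix (sites x samples), restricted to the sites
#'   retained by the observed frequency filter.
#' @param chromOfSite character vector of per-site chromosomes.
#' @param groupSizes integer sample counts, source first then derived.
#' @param snpsPerWindow window size in SNPs.
#' @param derivedOnly shuffle only the derived individuals, keeping the
#'   source group fixed.
#' @param maxRedraw bound on redraws before giving up.
#' @return list with `lambda` (descending eigenvalues) and `redraws`.
#' @export
permuteOnce <- function(gt, chromOfSite, groupSizes, snpsPerWindow,
                        derivedOnly = FALSE, maxRedraw = 100L) {
  nSnp <- nrow(gt)
  if (nSnp < snpsPerWindow)
    stop("fewer SNPs (", nSnp, ") than the window size")
  nSamp <- ncol(gt)
  bounds <- c(0L, cumsum(groupSizes))
  redraws <- 0L
  repeat {
    start <- sample.int(nSnp - snpsPerWindow + 1L, 1L)
    idx <- start:(start + snpsPerWindow - 1L)
    if (chromOfSite[start] != chromOfSite[idx[snpsPerWindow]]) {
      redraws <- redraws + 1L
      if (redraws > maxRedraw)
        stop("permutation redraw limit reached (", maxRedraw, ")")
      next
    }
    perm <- if (derivedOnly)
      c(seq_len(groupSizes[1L]),
        groupSizes[1L] + sample.int(nSamp - groupSizes[1L]))
    else sample.int(nSamp)
    popIdx <- lapply(seq_along(groupSizes),
                     function(g) perm[(bounds[g] + 1L):bounds[g + 1L]])
    cnt <- popCounts(gt[idx, , drop = FALSE], popIdx)
    freq <- cnt$alt / cnt$nChr
    if (anyNA(freq) || any(!is.finite(freq))) {
      redraws <- redraws + 1L
      if (redraws > maxRedraw)
        stop("permutation redraw limit reached (", maxRedraw, ")")
      next
    }
    X <- t(freq[, -1L, drop = FALSE] - freq[, 1L])
    norms <- sqrt(rowSums(X^2))
    if (any(norms == 0)) {
      redraws <- redraws + 1L
      if (redraws > maxRedraw)
        stop("permutation redraw limit reached (", maxRedraw,
             "): shuffled groups are repeatedly indistinguishable")
      next
    }
    X <- X / norms
    return(list(lambda = eigen(tcrossprod(X), symmetric = TRUE,
                               only.values = TRUE)$values,
                redraws = redraws))
  }
}

#' Build the permutation null distribution of eigenvalue statistics
#'
#' Runs `nPerms` independent label-shuffled random windows (see
#' [permuteOnce]) over the genotype data, using the same site filters as the
#' observed analysis, and collects the eigenvalue spectra.
#'
#' @param geno a [GenotypeData].
#' @param registry a [SampleRegistry].
#' @param nPerms number of permutations (default 10000).
#' @param snpsPerWindow window size in SNPs (default 200).
#' @param seed integer seed (required; permutations are stochastic).
#' @param minCalledFraction site filter matching [computeFrequencies].
#' @param derivedOnly see [permuteOnce].
#' @return a [NullDistribution].
#' @export
buildNull <- function(geno, registry, nPerms = 10000L, snpsPerWindow = 200L,
                      seed, minCalledFraction = 0.5, derivedOnly = FALSE) {
  stopifnot(nPerms >= 100)
  freqs <- computeFrequencies(geno, registry, minCalledFraction)
  keep <- match(paste0(as.character(seqnames(freqs)), ":",
                       start(rowRanges(freqs))),
                paste0(as.character(seqnames(geno)), ":",
                       start(rowRanges(geno))))
  gt <- assay(geno, "GT")
  src <- sourcePopulation(registry)
  derived <- derivedPopulations(registry)
  popIdx <- popIndexList(registry, colnames(gt))[c(src, derived)]
  gt <- gt[keep, unlist(popIdx), drop = FALSE]
  if (nrow(gt) < snpsPerWindow)
    stop("fewer retained SNPs (", nrow(gt), ") than the window size")
  chromOfSite <- as.character(seqnames(freqs))
  groupSizes <- vapply(popIdx, length, integer(1))
  seed <- as.integer(seed)
  set.seed(seed)
  m <- length(derived)
  values <- matrix(NA_real_, nrow = nPerms, ncol = m)
  redraws <- 0L
  for (i in seq_len(nPerms)) {
    p <- permuteOnce(gt, chromOfSite, groupSizes, snpsPerWindow,
                     derivedOnly = derivedOnly)
    values[i, ] <- p$lambda
    redraws <- redraws + p$redraws
  }
  if (redraws) message(redraws, " permutation window(s) redrawn")
  new("NullDistribution", values = values, m = as.integer(m),
      snpsPerWindow = as.integer(snpsPerWindow), seed = seed,
      redraws = redraws)
}

setMethod("show", "NullDistribution", function(object) {
  cat("NullDistribution:", nrow(object@values), "permutations, m =",
      object@m, ", window =", object@snpsPerWindow, "SNPs, seed =",
      object@seed, "\n")
})

#' Sorted null samples of the test statistic for eigenvector k
#'
#' @param null a [NullDistribution].
#' @param eigenvector eigenvector index k; the statistic is lambda_1 for
#'   k = 1 and the cumulative sum lambda_1 + ... + lambda_k otherwise.
#' @return ascending numeric vector of null statistics.
#' @export
nullStatistics <- function(null, eigenvector = 1L) {
  stopifnot(eigenvector >= 1, eigenvector <= null@m)
  sort(rowSums(null@values[, seq_len(eigenvector), drop = FALSE]))
}

#' Empirical add-one permutation p-value
#'
#' p = (1 + #\{null >= observed\}) / (1 + nPerms); never exactly zero.
#'
#' @param observed an [EigenResult], or the numeric statistic directly.
#' @param null a [NullDistribution] built with the same window size.
#' @param eigenvector eigenvector index k.
#' @return p-value in (0, 1].
#' @export
empiricalPvalue <- function(observed, null, eigenvector = 1L) {
  if (is(observed, "EigenResult")) {
    if (length(eigenValues(observed)) != null@m)
      stop("population count differs between observed window and null")
    if (length(observed@snpIdx) != null@snpsPerWindow)
      stop("window size differs between observed window and null")
    observed <- sum(eigenValues(observed)[seq_len(eigenvector)])
  }
  s <- nullStatistics(null, eigenvector)
  (1 + sum(s >= observed)) / (1 + length(s))
}

#' Call outlier windows against the permutation null
#'
#' Windows whose statistic exceeds the null's empirical `quantile` are
#' reported with their statistic, add-one p-value, eigenvector-1 loadings
#' and direction label.
#'
#' @param scan an [EigenScan].
#' @param null a [NullDistribution] with matching m and window size.
#' @param quantile outlier quantile in (0.5, 1) (default 0.999).
#' @param eigenvector eigenvector index k.
#' @return a `DataFrame` of outlier windows (possibly zero rows); the
#'   threshold used is stored in `metadata()$threshold`.
#' @export
callOutliers <- function(scan, null, quantile = 0.999, eigenvector = 1L) {
  stopifnot(quantile > 0.5, quantile < 1)
  if (scan@m != null@m)
    stop("population count differs between scan and null")
  if (scan@snpsPerWindow != null@snpsPerWindow)
    stop("window size differs between scan and null")
  stat <- scanStatistics(scan, eigenvector)
  s <- nullStatistics(null, eigenvector)
  thr <- unname(stats::quantile(s, quantile, type = 1))
  hit <- which(stat > thr)
  p <- vapply(stat[hit], function(x) (1 + sum(s >= x)) / (1 + length(s)),
              numeric(1))
  out <- scan@windows[hit, , drop = FALSE]
  out$statistic <- stat[hit]
  out$pvalue <- p
  metadata(out)$threshold <- thr
  metadata(out)$quantile <- quantile
  metadata(out)$eigenvector <- eigenvector
  out
}
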