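#' Construct a census trajectory
#'
#' @param population population label.
#' @param sizes per-generation diploid census sizes N_1 ... N_tau (generation
#'   1 is the founding bottleneck; sampling happens at generation tau).
#' @param n0 founding size; defaults to `sizes[1]`.
#' @return a [CensusTrajectory].
#' @export
CensusTrajectory <- function(population, sizes, n0 = sizes[1L]) {
  new("CensusTrajectory", population = as.character(population),
      n0 = as.integer(n0), sizes = as.integer(sizes))
}

#' @rdname CensusTrajectory
#' @param x a [CensusTrajectory].
#' @export
generations <- function(x) length(x@sizes)

setMethod("show", "CensusTrajectory", function(object) {
  cat("CensusTrajectory '", object@population, "': tau = ",
      length(object@sizes), ", N = ",
      paste(object@sizes, collapse = ", "), "\n", sep = "")
})

#' Map a dated census series onto per-generation sizes
#'
#' Converts census counts observed at known dates into one effective size per
#' generation by taking the harmonic mean of counts within each
#' generation-length interval (drift variance compounds as 1/N, so the
#' harmonic mean is the drift-equivalent size for an interval).
#'
#' @param dates `Date` vector (or coercible) of census observations.
#' @param counts census counts at those dates.
#' @param foundingDate date of introduction.
#' @param samplingDate date of sampling.
#' @param generationMonths generation length in months (default 7.9).
#' @param population population label for the result.
#' @return a [CensusTrajectory] with `tau = floor(months / generationMonths)`
#'   generations; a generation interval without census points inherits the
#'   nearest preceding interval's size.
#' @export
censusToGenerations <- function(dates, counts, foundingDate, samplingDate,
                                generationMonths = 7.9,
                                population = "pop") {
  dates <- as.Date(dates)
  foundingDate <- as.Date(foundingDate)
  samplingDate <- as.Date(samplingDate)
  months <- as.numeric(samplingDate - foundingDate) / 30.44
  tau <- max(1L, floor(months / generationMonths))
  genOf <- pmin(tau, 1L + floor((as.numeric(dates - foundingDate) / 30.44) /
                                  generationMonths))
  sizes <- rep(NA_real_, tau)
  for (g in seq_len(tau)) {
    inG <- counts[genOf == g & genOf >= 1L]
    if (length(inG)) sizes[g] <- 1 / mean(1 / inG)
  }
  for (g in seq_len(tau))
    if (is.na(sizes[g])) sizes[g] <- if (g > 1L) sizes[g - 1L] else
      stats::na.omit(sizes)[1L]
  CensusTrajectory(population, round(sizes))
}

#' Draw founder allele frequencies
#'
#' With a source frequency table, founding frequencies are the observed
#' source (minor-allele) frequencies. Without one, frequencies are drawn from
#' a neutral folded site-frequency spectrum with density proportional to
#' 1/p + 1/(1-p), truncated to [1/(2 ne), 0.5], via inverse-CDF sampling
#' (the CDF of that density is linear in logit(p)).
#'
#' @param nSnps number of SNPs to draw.
#' @param sourceFreqs optional [AlleleFreqTable] supplying observed source
#'   frequencies (its first `nSnps` sites are used; `nSnps = NULL` takes all).
#' @param ne effective size bounding the rarest sampled frequency.
#' @param seed optional integer seed.
#' @return numeric vector of founding frequencies in (0, 0.5].
#' @export
sampleFounderFrequencies <- function(nSnps = NULL, sourceFreqs = NULL,
                                     ne = NULL, seed = NULL) {
  if (!is.null(sourceFreqs)) {
    f <- sourceFreqs(sourceFreqs)
    if (!length(f)) stop("empty source frequency table")
    if (is.null(nSnps)) return(f)
    return(f[seq_len(min(nSnps, length(f)))])
  }
  stopifnot(nSnps >= 1, !is.null(ne), ne >= 2)
  if (!is.null(seed)) set.seed(as.integer(seed))
  lo <- 1 / (2 * ne)
  u <- stats::runif(nSnps)
  # CDF(p) = (logit(p) - logit(lo)) / (0 - logit(lo)) on [lo, 0.5]
  stats::plogis(stats::qlogis(lo) * (1 - u))
}

# deterministic diploid additive selection update: fitnesses 1, 1+s/2, 1+s
selectionUpdate <- function(p, s) {
  if (all(s == 0)) return(p)
  # marginal fitness of the tracked allele: p(1+s) + q(1+s/2)
  num <- p * (p * (1 + s) + (1 - p) * (1 + s / 2))
  den <- p^2 * (1 + s) + 2 * p * (1 - p) * (1 + s / 2) + (1 - p)^2
  num / den
}

#' Forward Wright-Fisher simulation conditioned on census sizes
#'
#' Simulates per-SNP allele-frequency trajectories: at each generation t the
#' allele count is a binomial draw of 2 N_t gametes at the current frequency
#' (generation 1 is the founding bottleneck at the founding frequency). SNPs
#' are unlinked and mutation-free; 0 and 1 are absorbing. An optional additive
#' selection coefficient applies the deterministic diploid update (genotype
#' fitnesses 1 : 1+s/2 : 1+s) to the expected frequency before each binomial
#' draw.
#'
#' @param founding numeric vector of founding frequencies (one per SNP).
#' @param census a [CensusTrajectory].
#' @param replicates number of independent replicate trajectories
#'   (default 200).
#' @param seed optional integer seed.
#' @param s selection coefficient(s) on the tracked allele: scalar or one
#'   value per SNP (default 0, neutral drift).
#' @return a [SimulationBatch] with the generation-tau frequencies.
#' @export
simulatePopulation <- function(founding, census, replicates = 200L,
                               seed = NULL, s = 0) {
  stopifnot(replicates >= 1, all(founding >= 0), all(founding <= 1))
  if (!is.null(seed)) set.seed(as.integer(seed))
  nSnp <- length(founding)
  sVec <- rep_len(s, nSnp)
  p <- matrix(founding, nrow = replicates, ncol = nSnp, byrow = TRUE)
  sMat <- matrix(sVec, nrow = replicates, ncol = nSnp, byrow = TRUE)
  for (N in census@sizes) {
    pSel <- selectionUpdate(p, sMat)
    p <- stats::rbinom(length(pSel), size = 2L * N, prob = pSel) / (2 * N)
    dim(p) <- c(replicates, nSnp)
  }
  new("SimulationBatch", population = census@population,
      founding = as.numeric(founding), final = p,
      tau = length(census@sizes),
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

#' @rdname SimulationBatch-class
#' @param x a [SimulationBatch].
#' @export
finalFreqs <- function(x) x@final

setMethod("show", "SimulationBatch", function(object) {
  cat("SimulationBatch '", object@population, "': ", nrow(object@final),
      " replicates x ", ncol(object@final), " SNPs, tau = ", object@tau,
      "\n", sep = "")
})
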