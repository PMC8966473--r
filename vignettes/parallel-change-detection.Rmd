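---
title: "Detecting parallel allele-frequency change: models and design choices"
author: "parafreq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting parallel allele-frequency change}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parafreq)
```

## The question

When several populations are founded from the same source and exposed to a
similar environmental shift, repeated evolution at the same loci is strong
evidence of selection. `parafreq` asks, window by window across the genome,
whether replicate derived populations changed allele frequency along a
*shared multivariate direction*, and whether the magnitude of per-SNP change
exceeds what census-conditioned genetic drift can explain. The motivating
study system is a replicated introduction experiment: one large high-predation
source population of Trinidadian guppies and four introduced populations
sampled roughly seven generations after founding, with about 20 diploids
sequenced per population.

## The change-vector eigenanalysis

For a window of $n$ SNPs (default $n = 200$) and $m$ derived populations, let

$$X_{ji} = p_{ji} - p_{0i},$$

the change in polarized allele frequency of population $j$ at SNP $i$
relative to the source. Each row is scaled to unit Euclidean length, so every
population contributes a *direction* of change and not a magnitude. The
$m \times m$ matrix $C = XX^\top$ then holds the pairwise correlations of
those directions (unit diagonal), and its eigendecomposition summarizes how
concentrated change is:

* all eigenvalues near 1 — each population drifted its own way;
* $\lambda_1$ near $m$ — all populations moved along one axis. Equal loading
  signs on the first eigenvector mean the movement was in the same direction
  (parallel); mixed signs mean opposite directions along the shared axis
  (antiparallel).

Because row lengths are 1, $\operatorname{tr}(C) = m$ exactly, which the
package enforces to $10^{-8}$ and the test suite checks against an
independent singular-value route ($\lambda_k = d_k^2$ for the singular values
$d_k$ of $X$).

Windows are defined in SNP-index space (exactly $n$ SNPs, consecutive, per
chromosome) rather than base pairs so that every window carries the same
information content as the permutation null. A terminal run shorter than $n$
is discarded: analysing it would break exchangeability with the null, which
only ever draws full-size windows. The eigenvector sign is arbitrary in exact
arithmetic, so the package fixes the first population's loading to be
non-negative; a loading within $10^{-10}$ of zero is reported as
indeterminate rather than forced into a parallel/antiparallel call.

Sites that are monomorphic across every population are removed before any
analysis: they carry no information and would contribute zero columns (and,
in degenerate windows, zero rows that have no direction at all; such windows
are excluded with a logged reason).

## The permutation null

Significance for a window statistic ($\lambda_1$, or the cumulative sum
$\sum_{i \le k}\lambda_i$ for eigenvector $k > 1$ — a single
$\lambda_k$ is not monotone in shared change) comes from permutation:
draw a random window of $n$ consecutive SNPs anywhere in the genome
(redrawing draws that straddle a chromosome boundary), shuffle all individual
labels, refill groups of the original sample sizes with one pseudo-source,
and recompute the whole pipeline. P-values use the add-one rule
$p = (1 + \#\{\text{null} \ge \text{obs}\})/(1 + N_\text{perm})$, so they
are never zero, and the default outlier call is the 99.9% null quantile with
10,000 permutations. Polarization is skipped inside permutations: flipping
an allele flips one column of $X$ in every row simultaneously and leaves
$C = XX^\top$ unchanged.

Two properties of this null are worth stating plainly.

*It is reproducible and exchangeable by construction*: the null windows have
exactly the SNP count of analysis windows, and identical seeds give
byte-identical outputs.

*It is conservative in the presence of drift.* All null rows share one
pseudo-source group, so under label exchange every pair of null change
vectors has correlation exactly $1/2$ regardless of the data. Observed
neutral rows share only the source *sampling noise*: their correlation is
$\sigma^2_{s}/(\sigma^2_{d} + 2\sigma^2_{s})$ where $\sigma^2_d$ is the
per-population drift variance and $\sigma^2_s$ the sample-frequency variance
— at most $1/2$, and strictly below it whenever drift occurred. No shuffle
of sampled individuals can manufacture the independent drift component, so
the null $\lambda_1$ distribution sits slightly above the observed neutral
one (about 2.50 vs 2.32 on average for $m = 4$, $n = 200$, 20 diploids per
population and seven generations of drift through realistic census sizes).
The practical consequence: false-positive rates run *below* nominal, and a
window called at the 99.9% quantile is, if anything, more extreme than the
label implies. The test suite measures this honestly rather than papering
over it; the calibration check at the 0.99 quantile documents the
conservativeness under the default study conditions, and p-value
monotonicity in $\lambda_1$ holds exactly. The `derivedOnly` shuffling
variant (source group held fixed) is provided but shares the same property.

## Census-conditioned drift simulation

The neutral expectation for per-SNP change comes from a per-SNP binomial
Wright-Fisher sampler: given per-generation diploid census sizes
$N_1 \dots N_\tau$ (generation 1 is the founding bottleneck), the allele
count at generation $t$ is $\mathrm{Binomial}(2N_t, p_{t-1})$. SNPs are
unlinked, mutation-free (negligible over fewer than ten generations), and 0
and 1 are absorbing. The simulator is exact for the model, so two closed
forms anchor the tests: the martingale property
$\mathbb{E}[p_\tau] = p_0$ and the variance law
$\operatorname{Var}(p_\tau) = p_0(1-p_0)\left[1 - \prod_t (1 -
\tfrac{1}{2N_t})\right]$.

Field censuses are counts at calendar dates, not generations.
`censusToGenerations()` converts a dated series using a generation length of
7.9 months (the system's estimate) and takes the *harmonic* mean of counts
within each generation interval, because drift variance compounds as $1/N$
and the harmonic mean is the drift-equivalent size of a fluctuating
interval.

An optional additive selection coefficient applies the deterministic diploid
update (genotype fitnesses $1 : 1 + s/2 : 1 + s$) to the expected frequency
before each binomial draw; this is used by the synthetic-data generator and
by the estimator-consistency checks, never by the neutral null.

## Standardized selection coefficients

Observed change is standardized for starting frequency as

$$s = \frac{2}{\tau}\,\ln\!\frac{p_\tau q_0}{p_0 q_\tau}, \qquad q = 1 - p,$$

the per-generation additive selection intensity that would deterministically
produce the observed logit change over $\tau$ generations (default
$\tau = 7$, matching the 6.1–7.6 generations separating founding and
sampling at a 7.9-month generation time). Because all frequencies are
polarized to the source minor allele, the signed values are comparable
across populations, and their per-SNP sum is maximized by change that is
large *and* co-directional. Three practical choices:

* **Clamping.** A lost or fixed final frequency has infinite log-odds; it is
  replaced by the detection floor $1/(2 n_\text{chr} + 1)$, where
  $n_\text{chr}$ is the population's sampled chromosome count — the
  frequency scale below which a sample of that size cannot see an allele.
  The clamp used is recorded in the output; changing it moves only SNPs that
  hit fixation. A source sample frequency of exactly 0 at a site polymorphic
  elsewhere is raised to the same floor (the scalar `standardizedS()`
  refuses $p_0 \in \{0, 1\}$ outright, since change from a fixed founder is
  undefined).
* **Two-sided thresholds.** Drift is symmetric on the logit scale, so
  neutral quantiles are taken on $|\sum_j s_j|$ by default; signed sums are
  retained in the output so directional statements (selection against the
  source minor allele gives negative sums) remain possible, and a one-sided
  option exists.
* **Sampling noise in the null.** Observed $s$ values are computed from
  finite samples (40 chromosomes per population, and a single shared source
  sample supplying $p_0$ for every population). The neutral quantiles can
  therefore resample each simulated final frequency binomially at the study
  sample sizes and draw a shared per-replicate pseudo-source sample.
  Resampled draws in which the tracked allele is absent (or fixed) in every
  pseudo-sample are discarded, mirroring the monomorphic-site filter applied
  to real data. With both mechanisms on, tier fractions match their nominal
  tails (0.99/0.999/0.9999, the tiers reported per SNP and summarized as
  observed-vs-expected counts per chromosome); with raw simulated
  frequencies the observed values would carry noise the null lacks and the
  tiers would over-call.

Estimator consistency is checked by simulating true additive selection
($s^* \in \{0.1, 0.3\}$, $N = 5000$, $\tau = 20$, $p_0 = 0.2$): the median
estimate recovers $s^*$ within 10%. The small systematic part of that gap is
expected — the estimator inverts logit-linear growth, while the exact
additive update advances the logit by between $\ln(1+s/2)$ and
$\ln\frac{1+s}{1+s/2}$ per generation.

## What the synthetic generator does and does not emulate

`syntheticDesign()`/`generateSynthetic()` produce the study structure used
throughout the tests: one source plus $m = 4$ derived populations, 20
diploids sampled from each, founder frequencies from a neutral folded
spectrum (density $\propto 1/p + 1/(1-p)$ truncated to $[1/(2N_e), 0.5]$,
$N_e = 1000$ as a plausible large-source value), seven generations of
binomial drift through per-population census trajectories that start at
founding sizes near 150–200 and grow with fluctuation into the low
thousands, 2% missing genotype calls, and optional selected loci with
parallel or antiparallel sign patterns (default pinned founder frequency
0.25 — selection on standing variation at moderate frequency, the regime the
eigenanalysis targets). Truth tables accompany every dataset.

Deliberately absent, and therefore untested here: linkage disequilibrium
(the eigenanalysis operates on frequencies; haplotype statistics are
external), new mutation, migration between populations, sex structure, and
sequencing/genotyping error beyond missingness. Passing tests show the
statistical machinery is correct under the model's own assumptions; they do
not show robustness to LD-induced correlation between windows, which on real
data is handled by the genomically matched random-window null.

## Numerical conventions and degenerate inputs

* Frequencies are computed over non-missing chromosomes; sites where any
  population's call rate falls below `minCalledFraction` (default 0.5) are
  dropped before polarization.
* A source frequency of exactly 0.5 polarizes to the alternate allele —
  deterministic and independent of file order.
* 75-kb ΔAF summary windows are half-open `[start, start + 75000)`, tiled
  from position 1; empty windows are reported with a SNP count of 0 and a
  missing statistic.
* Eigenvalues are reported in descending order; tolerances are $10^{-8}$ on
  the trace and orthonormality and $10^{-10}$ on eigenvalue non-negativity.
* Permutation windows are redrawn (with a logged count and a hard bound) on
  chromosome-boundary crossings and on shuffles that produce an all-zero
  change vector.

## Problem sizes used in the checks

The package's own validation runs at desk scale, chosen to keep the whole
suite in minutes while leaving the statistical checks well-powered: ~136,000
simulated SNPs (about 100,000 after filtering; ~500 analysis windows) with
2,000 permutations for null calibration, 10,000 replicates for the drift
variance laws, 2,000 replicates for estimator recovery, ~15,000 retained
SNPs with 200 simulation replicates for tier calibration, and 20 replicate
datasets for end-to-end power on a selected window ($s = 0.8$). The
permutation default for real analyses remains 10,000.

## Worked example

```{r example, eval = FALSE}
design <- syntheticDesign(snpsPerChrom = rep(2500L, 4L),
                          selectedSnps = 1001:1200, selectedS = 0.8)
sim <- generateSynthetic(design, seed = 1)
freqs <- computeFrequencies(sim$geno, sim$registry)
scan <- scanEigen(freqs, snpsPerWindow = 200L)
null <- buildNull(sim$geno, sim$registry, nPerms = 1000L,
                  snpsPerWindow = 200L, seed = 2)
callOutliers(scan, null, quantile = 0.99)
```

## Known limitations

* The permutation null is conservative under strong drift (quantified
  above); interpret near-threshold windows accordingly.
* Selection-coefficient standardization assumes the source sample frequency
  represents the founding frequency — reasonable for a large, recently
  sampled source, but biased for small or temporally distant sources.
* The drift simulator tracks frequencies, not pedigrees; it cannot produce
  identity-by-descent structure, and census sizes are taken at face value as
  effective sizes within each generation.
* All inference is per-window or per-SNP; no multiple-eigenvector joint test
  beyond cumulative sums is provided.
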