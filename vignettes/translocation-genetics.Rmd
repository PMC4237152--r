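---
title: "Methods: genetic diversity, capture and differentiation in conservation translocations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genetic diversity, capture and differentiation in conservation translocations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(translocgen)
```

# Scope and data model

`translocgen` analyses the population-genetic consequences of conservation
translocations: how much of a source population's diversity a founder
cohort captures, whether diversity changes over time, how populations
differentiate after isolation, and how large their effective sizes are.
It works from two marker types common in conservation programmes:

* **Codominant diploid microsatellite genotypes** (`geno_table`): allele
  labels are opaque positive integers; no fragment-size arithmetic is ever
  performed. A call is either two labels or wholly missing; half-calls are
  rejected so allele-frequency denominators stay unambiguous.
* **Multi-locus MHC presence profiles** (`mhc_profile_set`): class I
  alleles shared across duplicated loci make locus zygosity unobservable,
  so an individual's MHC genotype is the *set* of alleles detected.
  Frequency-based statistics therefore use **carrier counts** — the number
  of individuals carrying each allele — as haplotype-style observations.

Individuals are assigned to population-by-catch-year strata
(`sample_frame`), the unit of every analysis.

# Diversity statistics

**Expected heterozygosity** per locus uses the gene-copy unbiased
estimator $H_E = \frac{N_g}{N_g-1}\left(1-\sum_i p_i^2\right)$ over
complete calls. Missing data are handled by per-locus complete-case
denominators throughout the package: a call contributes to a locus's
spectrum only when both alleles were scored.

**Allelic richness** is standardized by hypergeometric rarefaction:
the expected number of distinct alleles among $g$ gene copies drawn
without replacement,
$A_g=\sum_i\left[1-\binom{N_g-N_i}{g}\big/\binom{N_g}{g}\right]$.
One global depth $g$ (default: the smallest complete-call count across
the loci and strata being compared) is used for all loci; per-locus
depths would change the meaning of the cross-stratum comparison and are
not reported by the field's standard tools in any recoverable way.

**MHC summaries** report the allele count $k$, the mean profile size
(alleles per individual), nucleotide diversity and the Ewens
sampling-formula $\theta_K$. With carrier counts $c_i$, $n=\sum c_i$ and
$q_i=c_i/n$:

* $\Pi = \frac{n}{n-1}\sum_{i\neq j} q_i q_j d_{ij}$ with $d_{ij}$ the
  nucleotide differences between allele sequences. $\Pi$ is reported
  **per amplicon**, not per site — with 255-bp alleles this puts values
  near 20, the scale on which such tables are conventionally printed.
* $\theta_K$ solves $\sum_{m=0}^{n-1}\theta/(\theta+m)=k$. The left side
  is strictly increasing in $\theta$, so bracketed root-finding is exact
  for practical purposes; $k=1$ gives 0 and $k=n$ diverges (reported as
  `Inf` with a warning). Using $n=\sum c_i$ — equivalently
  $\mathrm{round}(N\times\text{MHC/ind})$ — reproduces published worked
  examples of this estimator to the printed precision.

# Randomization test of temporal change

Two catch-year samples are pooled; `B` times (default 100 000) two
pseudo-samples of the original sizes are drawn *with replacement* and the
difference in the chosen statistic recomputed. The reported
$P=(1+\#\{|d^\ast|\ge|d_{obs}\}|)/(B+1)$; the $+1$ keeps $P>0$ and makes
the estimator valid for Monte-Carlo tests. Two-sided $|d|$ is the
default because the pooled-null design makes direction exchangeable; a
one-sided option counts only differences as extreme in the observed
direction. Pseudo-samples on which a statistic is undefined (e.g. an
all-missing locus) are redrawn and counted. Type-I error at
$\alpha=0.05$ is verified by null simulation in the acceptance suite.

# The genetic-capture planner

Translocations move individuals, so the sampling unit is the individual.
For each founder number $n$, `build_capture_curve()` draws `R = 1000`
replicate cohorts without replacement and records captured diversity:
mean distinct alleles per locus (microsatellites; over all loci or only
"diverse" loci with $\ge 4$ alleles) or total distinct MHC alleles.
Implementation detail worth knowing: one permutation per replicate is
reused across all $n$ (growing subsets). Prefixes of a uniform
permutation are exact uniform draws at every $n$, and the coupling makes
every replicate trajectory monotone — which is also how the monotonicity
invariant is demonstrated.

Reported "±" values are standard errors of the replicate mean
(SD$/\sqrt{R}$); SD and the 5th/95th percentiles are also emitted.
`min_founders()` inverts the curve at a target capture fraction;
`assess_founders()` compares an observed cohort against the replicate
distribution at its size with a lower-tail (capture-shortfall)
$P=(1+\#\{\text{replicates}\le\text{observed}\})/(R+1)$, counting ties
as extreme, and enumerates lost alleles with their source frequencies
(rare: frequency $<0.01$). For an allele carried by $m$ of $N$
individuals, the loss probability under uniform draws is exactly
$\binom{N-m}{n}/\binom{N,n}$, which the acceptance suite verifies by
exhaustive enumeration.

# Differentiation

**Microsatellite $F_{ST}$** is the Weir–Cockerham (1984) $\theta$:
variance components $a$, $b$, $c$ per locus and allele, combined as a
ratio of sums. This is the estimator equivalent of AMOVA-based pairwise
$F_{ST}$ in the standard desktop tools; exact agreement with any one
tool is not a goal, and calibration is instead by drift simulation
(mean $\hat\theta$ against $1-(1-1/2N_e)^t$). Negative estimates are
reported as computed. **MHC $F_{ST}$** uses the haploid analogue on
carrier counts. P values permute individuals between the two strata.

**Jost's $D$** uses Nei–Chesser-corrected $H_S$, $H_T$ with
harmonic-mean sample size and the two-stratum factor $s/(s-1)$.
Per-locus values are always returned; the multi-locus summary is the
harmonic mean when all per-locus values are positive and the arithmetic
mean otherwise, since the harmonic mean is undefined at the
near-zero/negative values typical of weak differentiation.

The **global test** of identical allele distributions across strata is a
permutation G-test (sum of per-locus G on allele-by-stratum tables,
individuals permuted among strata, default 30 000 permutations). It
stands in for the Markov-chain exact test of the classic tools: the null
and step count are the same, and its size is verified by type-I
simulation rather than by reproducing the chain.

The **Mantel test** correlates lower triangles of two stratum-level
matrices and permutes one matrix's labels jointly (upper tail). The
statistic matches vegan's implementation exactly; the permutation P is
checked against exhaustive enumeration on five labels.

# LD-based effective population size

For every locus pair, complete-case individuals give the Burrows
composite disequilibrium
$\hat\Delta=\frac{S}{S-1}\left(\overline{xy}/2-2\hat p\hat q\right)$ per
allele pair and $\hat r^2=\hat\Delta^2/[\hat p(1-\hat p)\hat q(1-\hat q)]$.
Alleles below the frequency floor (default 0.02, the conventional
precision/bias trade-off) are excluded, as is the complement of a rare
allele at an effectively biallelic locus; when every allele at a locus
passes, the most common is dropped as linearly redundant. The unweighted
mean $\hat r^2$ across comparisons is corrected for sample size and
inverted with the random-mating formulas of the LDNE lineage
($S\ge30$: $\hat r^2_{drift}=\hat r^2-1/S-3.19/S^2$,
$\hat N_e=[1/3+\sqrt{1/9-2.76\,\hat r^2_{drift}}]/(2\hat r^2_{drift})$;
a separate small-$S$ branch below 30). A corrected mean at or below zero
is reported as `Inf` — the data carry no drift signal. Confidence
intervals are parametric (chi-square with one degree of freedom per
comparison); jackknife intervals are not implemented. Only the
random-mating model is provided; the monogamy variant is out of scope.
Validation is by recovery on forward simulations (median over 200
replicates at true $N_e=50$ inside a pre-registered interval, and
monotone medians across $N_e\in\{25,50,100\}$), not by agreement with
any particular desktop tool.

# The synthetic world

`sim_config()`'s `warbler` preset states the world the analyses assume:

* **Microsatellites**: 163 source individuals, 30 loci with allele
  counts $7\times2, 16\times3, 4\times4, 2\times5, 1\times6$ and
  symmetric Dirichlet(1) frequencies. This yields mean $H_E\approx0.49$
  and allelic richness $\approx2.9$–$3.0$, with exactly seven "diverse"
  loci — the published profile of a severely bottlenecked island
  songbird. Missing calls at 2%.
* **MHC**: ten alleles over four duplicated loci with overlapping pools
  of five (each allele on at most two loci, so profile sizes are
  *structurally* confined to 2–8); within-pool Dirichlet(0.5)
  frequencies give a mean near 5 alleles/individual, within the
  published across-sample range (3.9–5.1). Allele sequences are a
  255-bp root mutated at 5% of sites, putting per-amplicon $\Pi$ near
  20. These constants were tuned once to those published values, before
  the test suite was written, and not revisited.
* **Demography**: founder cohorts drawn uniformly without replacement
  (the real translocations selected on condition and avoided first-order
  kin; neither is modelled), then discrete Wright–Fisher generations
  with $N_{t+1}=\min(K,\mathrm{round}(\lambda N_t))$, defaults
  $\lambda=1.5$, $K=250$ — plausible round numbers for rapid island
  population growth, since no quantitative rates are published.
  Offspring take one gamete from each of two uniformly chosen parents
  (selfing allowed); unlinked loci transmit independently within a
  gamete. Marginally this is exact multinomial Wright-Fisher sampling —
  heterozygosity decays as $(1-1/2N)^t$ — while the shared-parent
  structure generates the inter-locus LD that the $N_e$ module needs.
  No mutation, no migration (published inter-island dispersal is 0.1%,
  treated as zero), non-overlapping generations despite the species'
  overlapping ones: the analyses under test are agnostic to this, but
  it is a stated limitation.

What a green test establishes is therefore internal consistency with
this stated world — Hardy–Weinberg source, neutral drift, uniform
founder draws — not with features of real data the generator does not
emulate: null alleles, genotyping error, family structure among
founders, selection on MHC, or overlapping generations.

# Numerical choices and degenerate inputs

* Monte-Carlo P values all use the $+1/(B+1)$ form; tied replicate
  values count as extreme.
* Rarefaction uses log-scale binomial coefficients; $g$ beyond any
  locus's copy count is an error naming the locus.
* $\theta_K$ root-finding brackets $[10^{-12}, 10^k]$ with the upper
  bound expanded until it crosses; tolerance $10^{-10}$.
* Sampling one extra gamete-pool generation is the correct way to
  compare Weir–Cockerham $\theta$ to the drift expectation: the
  estimator's sampling correction removes exactly one multinomial round,
  so censusing the whole final generation would otherwise look like a
  one-generation-younger population.
* Negative $\theta$ and $D$ estimates are reported as computed; summary
  display floors at 0, CSVs never do.
* Pipeline stages derive seeds as a stable hash of the stage name folded
  into the global seed (`derive_seed()`), so adding or removing a stage
  never changes another stage's random stream.

# Known limitations

* GenePop population labels follow the shared-name convention; files
  with per-individual names get synthetic block labels (or supply a
  strata side table). Individual IDs are not preserved through a
  write/read round trip — genotypes, locus order and stratum assignment
  are.
* The permutation G-test is not the Markov-chain exact test; for very
  sparse tables its small-sample behaviour may differ even though its
  size is calibrated.
* LD-Ne point estimates at small sample sizes carry the documented
  upward bias of the method family when rare alleles sit near the floor;
  the recovery interval in the acceptance suite reflects that.
* The capture planner models uniform draws only; founder selection
  criteria used in practice could only reduce captured diversity
  relative to the curve if they correlate with genotype.
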