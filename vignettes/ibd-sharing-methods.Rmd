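---
title: "Methods: IBD segment sharing statistics in segshare"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: IBD segment sharing statistics in segshare}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(segshare)
```

## The statistic and its assumptions

`segshare` analyses identity-by-descent (IBD) segments that an upstream
caller (e.g. Refined IBD on phased SNP-array data) has already detected.
A detected segment connects two haplotypes of two individuals over a
physical interval; the package converts the interval to genetic length by
linear interpolation in a genetic map and works in centimorgans throughout,
because genetic length is what carries demographic signal: a segment
transmitted through `m` meioses has exponentially distributed length with
mean `100/m` cM, so for two descendants of an ancestor `g` generations back
(`m = 2g` meioses) the mean is `100/(2g)` cM.

For two groups A and B the mean sharing statistic is

\[
\bar{s}_{AB} \;=\; \frac{1}{n_{AB}} \sum_{(i,j)} t_{ij}, \qquad
\bar{p}_{AB} \;=\; \frac{\bar{s}_{AB}}{4G},
\]

where `t_ij` is the summed cM length of all retained segments between
samples i and j (over all four haplotype pairings), `n_AB` is the number of
unique retained pairs (`|A||B|` across groups, `n(n-1)/2` within), and `G`
is the genome length in cM. Dividing by `4G` — the four ways to pair
chromosomes between two diploid people — makes `p̄` a dimensionless
proportion of genome shared. Pairs with zero sharing contribute zeros to
the mean; both the retained and excluded pair counts are reported in every
summary so that the alternative convention (averaging over sharing pairs
only) can be recovered from `prop_pairs_with_ibd`.

Assumptions inherited from the upstream caller: segments are called on
autosomes from phased diploid data, short segments (< 2 cM) are unreliable,
and a LOD score accompanies each call. The package therefore restricts maps
and segments to autosomes 1–22 and exposes the two segment filters with
inclusive boundaries: retain iff `length_cM >= 2` and `lod >= 3` (defaults;
both configurable). The exclusion wording "shorter than 2 cM" makes 2.0 cM
itself a retained length.

## Relatedness exclusion: why the denominator is G

Close relatives dominate any mean sharing statistic if left in. The package
excludes a pair when its sharing fraction strictly exceeds 0.40. The
fraction is defined as total haplotype-level cM divided by `G` (not `2G` or
`4G`): under this convention the expected fractions are ≈ 1.0 for full
siblings (two parents × expected half the genome each), 0.5 for half
siblings and avuncular pairs, and 0.25 for first cousins. Only with the
`/G` scaling does a 0.40 cutoff separate exactly {full sib, half sib,
avuncular} (excluded) from first cousins (retained), which is the intended
behaviour of the filter. The boundary is strict ("more than 40%"), so a
fraction of exactly 0.40 is retained.

## Bootstrap over individuals

Confidence intervals for `p̄_AB` come from a nonparametric bootstrap that
resamples *individuals*, not pairs: each of the `B = 500` replicates draws
`|A|` individuals with replacement from A and `|B|` from B (up to the
original sample size of each group) and recomputes the statistic over the
resampled slots. Design details that the resampling scheme forces:

* **Duplicate draws** are distinct slots. Two slots holding the same
  original individual would form a "pair" sharing the whole genome; such
  self-identical slot pairs are dropped from the replicate statistic (they
  would in any case fall to the 40% rule), keeping replicates on the same
  support as the observed statistic.
* **Relatedness exclusion inside replicates** uses the original pair
  fractions, so a related pair stays excluded however often it is redrawn.
* **Interval**: 95% percentile, i.e. the 2.5% and 97.5% quantiles of the
  replicate distribution with linear interpolation between order statistics
  (`stats::quantile` type 7). Percentile is the simplest method consistent
  with reporting "mean and 95% confidence interval"; no BCa or studentised
  variant is attempted.
* **Seeding**: `bootstrap_panelwise` derives one child seed per group pair
  by a polynomial rolling hash of (master seed, sorted group labels), so
  results do not depend on the order in which comparison groups are listed.

The bootstrap targets sampling variation *of individuals*. It is therefore
calibrated when individuals genuinely differ in sharing propensity — which
real cohorts do (family clusters, village-level substructure). The
segment generator models this with optional per-individual multiplicative
rate effects (below); under pure pair-level noise with no individual
component the kernel of the pair-mean statistic is degenerate and any
individual-level bootstrap is conservative, a known property of resampling
U-statistics, not a defect of the implementation.

## Heat maps and networks

Heat maps display `log10(p̄)` with groups in a user-supplied order (for an
island transect, east to west). Base 10 makes cells readable as orders of
magnitude. Group pairs with zero mean sharing are masked (`NA`, drawn grey)
rather than floored at a pseudo-count, which would invent a rank.

The PCA network takes precomputed coordinates (Eigenstrat `.evec` or TSV;
the PCA itself is out of scope) and, for each sample, finds its `m` nearest
neighbours by Euclidean distance in the first `K` components **outside its
own population**, aggregating links into directed integer edge weights.
Defaults `K = 3`, `m = 3`: the neighbour count is deliberately small (the
construction is meant to expose each sample's closest foreign population,
not a dense graph) and both `K = 3` and `K = 5` views are supported.
Coordinates are used unweighted (no eigenvalue scaling — none is defined
for externally supplied coordinates), and distance ties are broken by
sample ID so the network is invariant to input order. Out-weights from
population P always sum to `m × |P|`; there are no self-loops by
construction. Export is a weighted TSV edge list (round-trips through
`read_network_edges`) or SIF for Cytoscape.

PC–geography association is reported as squared Pearson correlation, which
is invariant to the arbitrary sign of a PC axis and to affine unit changes
in either variable; constant inputs are an error rather than `NA`.

## Genotype QC conventions

* **Strand-ambiguous markers**: allele set {A,T} or {C,G}, removed
  order-insensitively, because their strand cannot be reconciled when
  merging array datasets.
* **Per-population missingness**: a marker is removed when its missing rate
  strictly exceeds 20% in *any* population; badly typed markers in one
  source dataset create artificial structure after merging.
* **MAF / HWE / missingness**: removal iff MAF < 0.01 (monomorphic markers
  have MAF 0 and are removed, not errored), exact Hardy–Weinberg p < 1e-6,
  or missingness > 0.02. The HWE test is the exact conditional test
  (enumeration of heterozygote counts given allele counts, summing
  configurations no more probable than the observed one), computed in log
  space; the chi-squared approximation is unreliable at p thresholds as
  extreme as 1e-6. It is applied to the pooled sample by default with a
  per-population option, and is symmetric under swapping homozygote labels.
* **LD pruning**: 50-marker windows advancing by 5 (familiar array-QC
  defaults), r² as squared Pearson correlation of dosages on
  pairwise-complete observations. Within a window the highest-r² pair above
  the 0.8 threshold is flagged repeatedly until none remains; the member
  with higher missingness is removed, ties broken by marker ID, making the
  prune deterministic. After pruning, an exhaustive within-window scan
  finds no remaining pair above the threshold (a property the test suite
  checks).

## The synthetic-data generators

The generators exist so that every pipeline stage is exercisable, with
known truth, from code alone. What they emulate — and what they do not:

* `simulate_segments`: per unordered sample pair, segment count
  ~ Poisson(λ(P,Q)) and lengths ~ Exponential(mean `100/(2 g(P,Q))` cM),
  placed uniformly on the map (chromosome chosen proportional to cM span)
  with LOD drawn above 3. This reproduces the *length–depth coupling* that
  the sharing statistics rely on, not demography: λ is a free parameter,
  not derived from population size, and overlapping segments for a pair
  are permitted and summed, matching how the statistic sums lengths.
  Optional per-individual rate effects `u_i ~ Gamma(mean 1, sd s)` multiply
  λ as `λ u_i u_j`, adding the individual-level heterogeneity that the
  bootstrap-over-individuals design presumes; because `E[u_i u_j] = 1`,
  expected sharing is unchanged. Default `s = 0` keeps the base model.
* `simulate_related_pair`: draws lengths from the exponential law for the
  relationship's meiosis count and tiles them along the genome until the
  total reaches `f·G` exactly (last segment truncated), so the realised
  fraction equals the relationship's expectation deterministically —
  sufficient for testing the 40% threshold without simulating meiosis.
* `simulate_pca_coords`: `PC1 = β·lon + N(0, σ²)`, higher components pure
  noise (optionally with per-population cluster offsets). The truth record
  carries the analytic `r² = β²·var(lon) / (β²·var(lon) + σ²)` for
  recovery tests.
* `simulate_genotypes`: Hardy–Weinberg background markers at frequencies
  uniform in [0.10, 0.45] with planted, disjoint failure sets — ambiguous
  alleles, exact minor-allele counts below the MAF cutoff, inbreeding-model
  heterozygote deficits (F = 0.8 at p = 0.5), exact per-population missing
  counts, and literal duplicate columns for LD — each recorded in a truth
  list so tests can assert that filters remove exactly the planted set.

What passing tests on these generators shows: the statistics, filters and
resampling machinery are correct against independent oracles under the
declared models. What it does not show: realism of any particular cohort —
real IBD data have detection error correlated with length, population-level
λ structure, genuine pedigree mixtures, and LD patterns far richer than
planted duplicates. Conclusions about real populations still require real
segments.

## Numerical and degenerate-input conventions

* Map interpolation clamps out-of-range bp to the terminal anchor's cM
  (no extrapolation — extrapolated rates can produce negative or inflated
  lengths); a segment's cM length is always the difference of its
  interpolated endpoints, so the bp inclusive/half-open convention does not
  affect lengths (endpoints are stored as found in the input).
* Unordered pairs are canonicalised with the lexicographically smaller
  sample ID first; self-pairs are rejected at parse time.
* Zero retained pairs (everything excluded) is a hard error, never a silent
  `NaN`; bootstrap replicates with no retained pairs are dropped with a
  warning.
* All generators run under a locally scoped RNG (`set.seed` applied and the
  caller's `.Random.seed` restored), so identical seeds give byte-identical
  output regardless of surrounding code.

## Problem sizes used by the test suite

The suite's end-to-end checks use cohorts chosen to make oracle comparison
exact and simulation-based checks statistically sharp: 4 populations × 10
samples (~2,000 filtered segments) for brute-force equivalence; 100
simulated pairs per relationship class for the exclusion pattern; 200
simulated two-population cohorts (25 + 25 individuals, λ = 10, g = 20,
individual-effect sd 0.6) × 500 bootstrap replicates for coverage, judged
against the exact binomial 99% band around 0.95; 100 replicates for
sharing-rank recovery across g ∈ {10, 50, 200}; n = 200 samples for
network-oracle and geo-correlation calibration; and the full enumeration of
all genotype-count triples with n ≤ 50 for the exact HWE test.

## Known limitations

* Segment *detection* is out of scope; garbage segments in, garbage
  statistics out. The LOD and length filters are the only defence.
* The bootstrap assumes groups are disjoint sample sets; comparing
  overlapping groups is rejected.
* `ld_prune` recomputes window correlation matrices in R; adequate for
  array-scale marker counts in the tens of thousands, not for sequencing
  density.
* The related-pair generator targets expected fractions; it does not model
  the variance of realised sharing among, e.g., real first cousins, so it
  cannot be used to study misclassification rates near the threshold.
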