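---
title: "Noninvasive microsatellite genotyping of brown bears: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Noninvasive microsatellite genotyping of brown bears: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bearid)
```

## The problem

Hair left by brown bears on rubbing trees, creosote-treated power poles,
barbed wire and corral hair traps can be genotyped at microsatellite loci
without ever handling an animal. Such DNA is scarce and degraded, so three
problems dominate the analysis: genotyping *errors* (allelic dropout — the
stochastic loss of one allele of a heterozygote, biased towards the longer
fragment; stutter shifts of one repeat unit; occasional false alleles),
genotyping *failure* (loci that do not amplify at all, at rates that depend
strongly on the hair source), and *resampling* (a mobile bear deposits hair
at many sites, so samples are not individuals).

`bearid` implements the full workflow used for the Grand Kaçkar Mountains
(GKM) population in northeastern Anatolia — 154 samples, ten microsatellite
loci (`G10C, G10X, UarD1585, UarT739, UarD3139, UarD3684, G1D, Mu05, Mu23,
Mu50`) plus the Y-linked sexing locus SRY — together with a synthetic-data
generator that emulates that campaign, so every stage is testable without
any external data.

## Replicate consensus

Each noninvasive sample is genotyped in two parallel PCR replicates. A
locus is accepted when all non-missing replicate calls agree; a locus
confirmed by only one replicate (the other failed) is accepted but flagged
`confirmed_single` — discarding it would be stricter than the retention
counts of real campaigns suggest. If *any* locus mismatches between the
two replicates, the whole sample is re-extracted and genotyped in a second
replicate pair; a mismatch in the second round discards the sample. The
mismatch scope is deliberately the whole sample, not the single locus,
mirroring the re-extraction protocol of the field study. Tissue samples
(one replicate of good DNA) pass through unchanged.

A sample counts as successfully genotyped when at least 8 of the 10 loci
score (`filter_by_locus_coverage()`, default `min_loci = 8`).

Within a replicate, a call with exactly one observed allele is stored as a
*provisional homozygote* with a `single_allele` flag rather than discarded:
this is precisely how dropout manifests, and keeping the call (flagged)
lets the identification rules reason about it.

## Individual identification

Consensus genotypes are clustered into unique individuals with a matching
rule of at most two allele mismatches (`alleleMismatch = 2` in the
`allelematch` tradition). Per locus, the mismatch count is
`2 - |multiset intersection|` of the two allele pairs; loci missing in
either genotype are wildcards (0 mismatches) but are recorded. A pair is
the *same* individual only when every difference is attributable to a
recognised artifact:

* **dropout** — one genotype heterozygous, the other homozygous for the
  *smaller* allele (large fragments amplify worse, so true large-allele
  dropout leaves the small allele);
* **size shift** — the two unshared alleles differ by exactly one repeat
  unit (stutter);
* **missing data** — the locus is missing in exactly one genotype.

Anything else is `unexplained` and forces a *distinct* verdict. Matching
pairs form a graph; individuals are its connected components. When
chaining produces a component containing a pairwise *distinct* verdict,
the component is flagged and split at its weakest edges (largest mismatch
count) until consistent — the field study resolved such cases by manual
curation; flag-and-split is the reproducible analogue. The consolidated
genotype prefers, per locus, confirmed heterozygote calls over
dropout-suspect homozygotes, and non-missing over missing; ties go to the
most frequent call, then input order (which is itself deterministic:
individuals are numbered by first member sample id).

Sex is called from SRY: all member samples positive → male, all negative →
female. Mixed evidence is resolved towards male when positives are in the
majority (SRY dropout in degraded hair is expected), but a *minority* of
positives against several negative exact matches is reported as a
`conflict`, not silently resolved — the analogue of a female genotype whose
one discordant sample amplified SRY.

Genotypes with missing data at more than one locus are discarded before
population-genetic statistics (`filter_for_analysis()`, default 1).

## Per-locus statistics

For the retained unique genotypes, `locus_stats_table()` assembles:

* observed heterozygosity and *unbiased* expected heterozygosity
  `(2n/(2n-1)) (1 - Σ p_i²)` (the small-sample correction used by the
  classic population-genetics packages; the biased form is also exposed);
* a **Monte-Carlo exact HWE test**: Pearson chi-square of genotype counts
  against Hardy–Weinberg expectations, with the null distribution obtained
  by re-pairing the observed gene copies; with 7–10 alleles on ~40
  individuals the asymptotic chi-square is invalid. Default 10,000
  permutations; `p = (1 + #{null ≥ obs}) / (B + 1)`;
* the **Chakraborty null-allele estimate** `r = (H_E − H_O)/(H_E + H_O)`,
  flanked by a one-sided Monte-Carlo test of homozygote excess (simulated
  HWE samples at the observed frequencies) — the null-allele screening
  step;
* **Weir–Cockerham F_IS** from single-population variance components
  (`b = n/(n−1)[p(1−p) − (2n−1)/(4n) h̄]`, `c = h̄/2`;
  `f = 1 − Σc/Σ(b+c)` over alleles, and over loci for the multilocus
  value);
* **probability of identity**: biased `2a₂² − a₄`, the sibling form
  `0.25 + 0.5a₂ + 0.5a₂² − 0.25a₄`, and the small-sample unbiased
  estimator with `N` = gene copies. The unbiased formula equals, exactly,
  the probability that two genotypes assembled from four gene copies drawn
  *without replacement* from the sample match — we verified this by full
  enumeration, and the test suite uses that resampling scheme as its
  Monte-Carlo oracle. Note the unbiased value is *not* always above the
  biased one (it is not for concentrated frequency spectra at small `N`);
  only the sibling form is an upper bound, and only that bound is asserted.
  Cumulative values are products over loci, clipped to (0, 1].

## Population structure

* `pairwise_fst()`: Weir–Cockerham θ summed over alleles and loci, with
  significance from permuting individuals between groups (10,000
  permutations by default). One caution learned from simulation: the
  *realised* divergence of two populations drawn from a Balding–Nichols
  prior is itself random with few degrees of freedom (sd ≈ 0.02 around a
  target of 0.10 with 10 loci), so parameter-recovery checks average θ
  over replicate simulations rather than gambling on one draw.
* `shared_allele_distance()` / `kosman_dissimilarity()`: per pair,
  `1 − Σ shared_l / (2 L_shared)` and the mean of per-locus
  `1 − shared_l/2`; algebraically identical on complete data (a property
  the tests assert), but reported separately because the field uses both
  names. Pairs with no shared scored loci are undefined and flagged.
* `neighbor_joining()`: Saitou–Nei NJ (via \pkg{ape}); negative branch
  lengths are clamped to zero with the excess moved to the adjacent
  branches.
* `pca_genotypes()`: PCA of allele dosages (0/1/2), missing entries
  imputed with the allele's mean dosage, columns centred.
* `dissimilarity_vs_distance()`: Kosman dissimilarity against great-circle
  distance (haversine, earth radius 6,371 km) over all genotyped *samples*
  — not unique individuals — so that a bear resampled across provinces
  contributes a zero-dissimilarity pair at long distance. A running mean
  in a 20 km sliding window (the smoothing width is our choice; the field
  study did not state one) and a Mantel permutation test summarise
  isolation by distance.
* `admixture_cluster()`: a Gibbs sampler for the standard admixture model
  — Dirichlet(1) cluster allele frequencies, per-individual membership
  `q ~ Dirichlet(α)`, latent per-gene-copy origins. Model support uses
  `lnP = mean(lnL) − var(lnL)/2` over post-burn-in sweeps. The admixture
  parameter α is *sampled* (Metropolis step, uniform prior on (0, 10])
  rather than fixed: with α fixed at 1, per-individual memberships overfit
  panmictic data and `lnP(K)` is maximal at K ≥ 2 in most replicates;
  letting α adapt (large under panmixia, collapsing `q` to uniform)
  restores K = 1 selection, which is also how the reference Bayesian
  clustering software behaves. A numeric `alpha` still fixes it. The
  spatially explicit variant used as a secondary analysis in the field
  study is out of scope here; its published outcome was inconclusive.

## Genotyping success

`tabulate_success()` cross-tabulates the ≥8-loci success indicator against
source or year: by convention the source analysis uses noninvasive samples
only (N = 144 in the study frame) and the year analysis all hair samples
(N = 147). `chi_square_independence()` is the plain Pearson test without
continuity correction — required to reproduce the published 2×2 statistic
(15.81) exactly — and warns (not errors) on expected counts below 5. The
published pooled comparison contrasts {rubbing trees, barbed wire} against
{poles}, hair traps excluded; `pool_columns()` reproduces it. For the 2×4
source table the statistic is 19.09 on 3 df, for which the correct p-value
is ≈ 2.6 × 10⁻⁴; the package always reports its own computed p.

## The synthetic-data generator

`generate_study_like_dataset()` reproduces the GKM sampling frame exactly:
154 samples (7 tissue, 3 invasive capture hairs, 144 noninvasive split
72/53/12/7 over poles/trees/barbed wire/hair traps), 48 individuals in two
provinces (42 + 6, one mobile individual sampled in both, centres ~170 km
apart), collection years with the published margins, and sex ratio 83.3%
male. Population genetics follow a Balding–Nichols model: ancestral
frequencies Dirichlet(1) over the panel's observed allele counts (7–10 per
locus), subpopulation frequencies Dirichlet(`p(1−F)/F`) with
`F = target_fst = 0.005` (negligible differentiation, as observed), and
optional inbreeding via an identical-by-descent coin flip per locus.

The error process injects, per replicate: locus-level amplification
failure at a *source-specific* rate, per-copy dropout, per-copy ±1-repeat
stutter, and per-locus false alleles. Two design points matter:

* **Failure carries degradation; residual error is small.** Under the
  whole-sample two-round discard rule, *any* per-locus disagreement
  anywhere in the 10-locus profile triggers re-genotyping or discard, so
  the per-locus disagreement rate caps attainable success at roughly
  `c(2 − c)` with `c = (1 − p_mismatch)^10`. Barbed-wire samples succeed
  83% of the time in the study, which is only reachable if conditional
  per-locus error is low. The generator therefore uses dropout 1% per
  copy, stutter 0.2% per copy and false alleles 0.2% per locus as the
  residual error on amplifiable loci, and lets the calibrated failure
  rates absorb source-dependent DNA quality.
* **Calibration to the published success rates.** Given those residual
  rates, `calibrate_locus_failure()` solves by bisection for the per-locus
  failure probability that makes a sample pass the two-round rule and the
  8-of-10 filter with the published per-source probability (26.39%,
  54.72%, 83.33%, 42.86%; ~90% for capture hair, 100% for tissue),
  simulating the full pipeline under common random numbers so the result
  is deterministic. Seeds control everything: the same seed yields a
  bit-identical dataset.

The truth table (individual ↔ sample map, true genotypes, injected-error
counts) supports exact scoring of the identification stage
(`compare_to_truth()`: a truth individual is *detectable* with ≥1 retained
sample, *recovered* when some identified individual is purely its samples;
*splits* and *lumps* count fragmentation and mixing).

What the generator does **not** emulate: spatial home-range movement
(coordinates are Gaussian jitter around province centres), year effects on
success (the study found them; the generator's failure rates are
year-independent), pedigree structure/relatedness, null alleles as a
persistent locus property, and per-sample DNA-quality heterogeneity within
a source. Passing tests therefore show the *methods* behave correctly
under the study's sampling frame and error magnitudes — not that every
feature of real hair-snag data is captured.

## Numerical conventions and problem sizes

Monte-Carlo p-values use `(1 + #{≥ obs})/(B + 1)` throughout, with ties
counted conservatively (`≥ obs − 1e-12`). Distance matrices assert
symmetry and zero diagonals on every call. The identity-probability
products are clipped to (0, 1]. Consensus and clustering are invariant to
replicate order and to input sample order (tested properties).

The test-suite simulations use: n = 500 individuals for inbreeding
recovery, n = 100–200 across two demes (averaged over 12 replicate draws)
for θ recovery, 1,000 replicates × 399 permutations for the HWE type-I
error, 10⁶ resampled pairs for the identity-probability oracle, 60
individuals × 1,500 sweeps for admixture assignment accuracy, and 12
panmictic replicates × 800 sweeps for K-selection — sizes chosen to give
stable Monte-Carlo bounds on one CPU.

## Known limitations

* The matching rule is combinatorial, not likelihood-based; relatedness
  (full siblings sharing most alleles) is handled only through the
  P_IDsib safeguard on the panel's resolving power.
* The Chakraborty estimator assumes HWE apart from the null allele;
  inbreeding or Wahlund effects inflate it.
* The admixture sampler runs single-chain; for real analyses compare
  several seeds (the workflow scripts do).
* Genepop export recodes alleles by rank, which loses absolute fragment
  sizes (the code map is returned as an attribute).
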