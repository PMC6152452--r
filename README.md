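# bearid

Individual identification and population genetics from noninvasively
collected brown bear microsatellite genotypes.

## The problem

Monitoring elusive large carnivores usually means genotyping hair left on
rubbing trees, creosote-treated power poles, barbed wire and corral hair
traps. The DNA is scarce and degraded, so the analysis must deal with three
things at once: genotyping **error** (allelic dropout producing false
homozygotes, one-repeat stutter shifts, occasional false alleles),
source-dependent genotyping **failure**, and **resampling** — one mobile
bear leaves hair at many sites, so samples are not individuals.

`bearid` implements the workflow used for the Grand Kaçkar Mountains (GKM)
brown bear population in northeastern Anatolia (ten microsatellite loci
plus the Y-linked SRY sexing locus), for field ecologists and conservation
geneticists running similar hair-snag campaigns:

1. **Replicate-consensus genotyping** — two PCR replicates per sample; any
   locus mismatch demands a second replicate pair; a second mismatch
   discards the sample; success = ≥ 8 of 10 loci scored.
2. **Individual identification** — genotypes within 2 allele mismatches are
   merged when every difference is attributable to large-allele dropout,
   stutter (±1 repeat unit) or missing data; SRY-based sexing with explicit
   conflict reporting.
3. **Per-locus statistics** — observed and unbiased expected heterozygosity
   (H_O, H_E), Monte-Carlo exact Hardy–Weinberg tests, Chakraborty
   null-allele estimates r = (H_E − H_O)/(H_E + H_O) with homozygote-excess
   tests, Weir–Cockerham F_IS, and probabilities of identity P_IDunb and
   P_IDsib (cumulative over loci).
4. **Population structure** — permutation-tested Weir–Cockerham F_ST,
   shared-allele / Kosman–Leonard distances with neighbor-joining trees,
   PCA of allele dosages, genetic dissimilarity vs geographic distance, and
   a Gibbs sampler for the Bayesian admixture model (K-selection via
   lnP = mean lnL − var lnL / 2).
5. **Sampling success** — chi-square contingency analysis of genotyping
   success by hair source and year.
6. **A synthetic-data generator** reproducing the GKM sampling frame (154
   samples, 48 bears, two provinces, published per-source success rates)
   with a truth table for exact scoring of the pipeline.

## Worked example

```r
library(bearid)

sim  <- generate_study_like_dataset(seed = 1)   # synthetic GKM-like campaign
ds   <- consensus_genotypes(sim$dataset)        # two-round replicate rule
part <- filter_by_locus_coverage(ds, min_loci = 8)
ind  <- identify_individuals(part$retained)     # unique genotypes + sex
kept <- filter_for_analysis(ind, max_missing_loci = 1)

g  <- mlg_matrix(kept$genotypes, gkm_panel(), id_col = "individual_id")
st <- locus_stats_table(g, n_permutations = 2000, seed = 1)
```

which prints (via `print(ds)`, `print(ind)`, `head(st)`):

```
<bear_dataset>
  samples:   154 (barbed_wire=12, capture_hair=3, hair_trap=7, pole=72, tissue=7, tree=53)
  loci:      10
  replicates: 325 genotyping runs
  consensus: computed (153 samples ok, 1 discarded)
<bear_individuals> 39 unique genotypes from 65 samples
  sex: female=1, male=38
     locus n_alleles h_obs h_exp hwe_p null_ch   f_is
1     G10C         9  0.93  0.83  0.40  -0.055 -0.119
2     G10X         9  0.86  0.81  0.38  -0.026 -0.055
3 UarD1585        10  0.79  0.83  0.45   0.027  0.053
4  UarT739         5  0.54  0.59  0.15   0.052  0.101
```

65 of 154 samples survive consensus and the 8-of-10 coverage filter and
collapse to 39 unique genotypes (the campaign resamples bears heavily);
`h_obs`/`h_exp` are the per-locus heterozygosities of the retained
genotypes, `hwe_p` the Monte-Carlo exact HWE p-value, `null_ch` the
Chakraborty null-allele estimate and `f_is` the Weir–Cockerham inbreeding
coefficient. The cumulative identity probabilities of the panel,

```
cumulative P_IDunb = 5.54e-12, P_IDsib = 8.55e-05
```

say that even full siblings are essentially never confounded across ten
loci. Between the two provinces the differentiation is nil, as expected at
the simulated F_ST of 0.005:

```
province theta = -0.0109 (P = 0.74)
```

## The analysis workflow

`analysis/01_simulate.R` … `06_sampling_success.R` run the six stages as a
narrative pipeline from the repository root, writing tables under
`results/` (genotype CSV + truth JSON, consensus QC, individuals,
the per-locus summary statistics, F_ST / NJ tree / PCA / admixture outputs,
and the success contingency tables with their chi-square tests).

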