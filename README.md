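# ibispop

Population-genomic and forensic-marker statistics for severely
bottlenecked populations.

Conservation programmes that rescue a species from a handful of founders —
the crested ibis, re-founded from two breeding pairs, is the textbook
case — need to quantify what the bottleneck did to the genome and to manage
breeding afterwards. `ibispop` implements the downstream statistics such a
programme runs on SNP and STR data, together with a Wright–Fisher
simulator that generates every input with known ground truth, so each
statistic can be validated against an exact expectation before it touches
real data.

## What it computes

**Genome diversity** (per genotype matrix)

- per-individual heterozygosity (het sites / callable bp)
- Watterson's estimator `θ_S = K/(aL)`, `a = Σ_{i=1}^{n−1} 1/i`
- the windowed fixation scan: pooled heterozygosity per 500-kb window
  `Hp = 2 Σn_MAJ Σn_MIN / (Σn_MAJ + Σn_MIN)²`, Z-standardized to `ZHp`,
  with putative sweep/fixation windows called at `ZHp ≤ −2.326`
  (the lower 1% normal quantile) and overlapping genes annotated
- heterozygosity-decay regression `H_t/H_0` against recovery time, with
  slope CI, Pearson r and p-value
- neutral mutation rate from divergence:
  `μ = divergence × generation_time / (2 × divergence_time)`

**Functional variants**

- codon-level SNP classification (synonymous / missense / stop-gain /
  stop-loss / start-loss) on both strands, codons split across exons
- per-genome NS/S heterozygosity ratios; derived-allele-frequency spectra
  by effect class (ancestral allele from an outgroup)
- per-gene loss-of-function enrichment between species groups by exact
  Fisher tests (one-sided each direction, optional BH correction)

**Linkage & structure**

- two-locus `r²` via EM haplotype-frequency estimation on unphased
  genotypes; LD-decay curves with Haploview-style filters (max distance,
  MAF, call rate, exact-HWE) and the half-maximum decay distance
- Weir–Cockerham `F_ST` with per-locus variance components and
  ratio-of-averages genome-wide combination

**Forensic STR toolkit** (DNA identification / DIP panels)

- perfect-repeat scanner, per-locus allele summaries and expected
  heterozygosity, polymorphic-locus fractions by unit size
- match probability / discrimination power, exclusion probability by
  exact triplet enumeration, paternity index and probability of
  paternity, W-linked (31-bp insertion) sex calling

**Synthetic data** — forward Wright–Fisher populations under
piecewise-constant demography (bottlenecks), infinite-sites mutation with
known ancestral alleles, optional recombination; managed-breeding
pedigrees; stepwise-mutation STR loci; CDS landscapes with effect-labelled
implanted variants. All bit-reproducible under a seed.

`run_pipeline()` chains everything (simulate or read inputs → diversity →
scan → LD → FST → effects → STR panel) into one reproducible report.

## Worked example

A toy managed-recovery scenario: a population crashes to 10 diploids for
five generations, recovers to 100, and ten individuals are sampled at
generation 20 alongside a 22-locus STR panel typed on a four-cohort
pedigree:

```r
library(ibispop)
report <- run_pipeline(list(
  scenario = list(
    founder_pairs = 2, generations = 3,
    wf = list(epochs = data.frame(N = c(200, 10, 100),
                                  duration = c(2, 5, 13)),
              mu = 1e-7, L = 1e6, init_sites = 3000,
              sample_times = 20, sample_sizes = 10),
    str = list(n_loci = 22, mu = 0.01),
    cds = list(genome_length = 5e4, n_genes = 8, n_syn = 100)),
  params = list(min_snps_per_window = 5),
  seed = 42))
report
#> pipeline_report with stages: diversity, scan, ld, fst, effects, str
#>   scan: 0/20 windows flagged (0.0%)
#>   str: combined PD 1.0000, combined PE 1.0000

report$diversity$theta
#> Watterson theta_S = 0.0007529 per bp (K = 2671, n = 20, L = 1e+06, a = 3.5477)

summary(report$diversity$het_per_sample$het)
#>      Min.   1st Qu.    Median      Mean   3rd Qu.      Max.
#> 0.0000010 0.0000050 0.0014895 0.0009015 0.0015040 0.0015080
```

The heterozygosity summary is worth reading closely: after a 5-generation
crash to 10 diploids only a few founder haplotypes survive, so four of the
ten sampled individuals are essentially homozygous genome-wide (het rate
~10⁻⁶) while the rest carry two distinct surviving haplotypes (~1.5×10⁻³)
— the identity disequilibrium a real post-bottleneck population shows.
The 22-locus STR panel still separates every individual (combined
discrimination power 1.0000) and excludes random non-fathers with
combined probability 1.0000.

Heterozygosity-decay regression on a small monitoring series:

```r
fit <- decay_regression(ht_h0_series(
  het  = c(2.1, 1.9, 2.0, 1.7, 1.6, 1.45, 1.4) * 1e-3,
  time = c(0, 0, 0, 6, 6, 12, 12)))
fit
#> Ht/H0 decay: slope = -0.02426 per unit time (95% CI -0.03201..-0.01652), r = -0.964, p = 0.000478, n = 7
```

meaning ~2.4% of founding heterozygosity is lost per time unit in this
series, with the confidence interval excluding zero.

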