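---
title: "Population-genomic statistics for bottlenecked populations: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population-genomic statistics for bottlenecked populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ibispop)
```

## Scope and motivation

`ibispop` implements the downstream population-genomic analyses used to
characterize a population that has passed through a severe bottleneck — the
canonical case being the crested ibis, re-founded from two breeding pairs
and recovered under managed breeding.  The package covers four statistical
families and a simulator that generates every input with known ground
truth:

1. **Genome diversity** — per-individual heterozygosity, Watterson's
   $\theta_S$, the windowed pooled-heterozygosity ($H_p$/$ZH_p$) fixation
   scan, and $H_t/H_0$ decay regression.
2. **Functional variants** — codon-level SNP classification, per-genome
   NS/S ratios, derived-allele-frequency spectra, and per-gene
   loss-of-function enrichment.
3. **Linkage and structure** — EM-based two-locus $r^2$, LD-decay curves
   with half-maximum distances, and Weir–Cockerham $F_{ST}$.
4. **Forensic STRs** — locus summaries, discrimination power, exclusion
   probability, paternity index, and W-linked sex calling for a
   DNA-identification (DIP) marker panel.

Genome assembly, read mapping, variant calling and demographic-inference
tools (PSMC-style analyses) are deliberately out of scope: the package
consumes genotypes, counts and tables, not reads.

## Coordinate conventions

Internally every interval is 0-based half-open (BED semantics); VCF input
and output remain 1-based.  The single conversion point is
`assign_windows()`: a VCF site at position $p$ occupies 0-based coordinate
$p-1$, so under non-overlapping tiles of width $w$ it falls in the window
starting at $\lfloor (p-1)/w \rfloor \, w$.  Although windowed scans of
this kind are often described as "sliding", a genome of ~1.26 Gb tiled at
500 kb yields the ~2,514 windows such scans report, which is tiling
arithmetic; `make_windows()` therefore tiles by default and accepts a
`step` argument for true sliding.  A trailing window shorter than `width`
is kept but flagged `partial`, and flagged windows are excluded from
genome-wide standardization — the analysis is silent on this case, and
exclusion avoids length-biasing the tails of the $H_p$ distribution.

## The fixation scan

For each window the pooled heterozygosity is computed once from summed
major/minor allele read counts,

$$H_p = \frac{2\,\sum n_{MAJ} \sum n_{MIN}}{(\sum n_{MAJ} + \sum n_{MIN})^2},$$

with major/minor orientation fixed per SNP *before* summation (ties
contribute symmetrically).  When AD-style read counts are unavailable,
`counts_from_genotypes()` substitutes carried-allele counts (2 per
homozygote, 1 per heterozygote) — a documented fallback that keeps the
scan usable on genotype-only inputs.  Missing genotypes never enter a
numerator or denominator anywhere in the package.

$ZH_p = (H_p - \mu_{H_p})/\sigma_{H_p}$ uses the **sample** (n−1)
standard deviation; the convention is unstated in most descriptions of the
scan and the sample form is the standard Z-transform, so tests assert it
explicitly.  Windows with fewer than `min_snps_per_window` (default 10)
SNPs are flagged and excluded from $\mu_{H_p}, \sigma_{H_p}$ — near-empty
windows otherwise dominate the tails.  The sweep threshold defaults to
`normal_quantile(0.01)` $= -2.326$, i.e. the lower 1% tail of the standard
normal.  Sex-chromosome scaffolds should be excluded by the caller (label
them and subset), mirroring standard practice.

## Diversity statistics

Watterson's estimator is the textbook
$\theta_S = K/(aL)$ with $a = \sum_{i=1}^{n-1} 1/i$ over $n$ sampled
chromosomes; it is undefined below $n = 2$ and errors accordingly.
Per-individual heterozygosity is a count of heterozygous genotypes over a
caller-supplied callable length, because callable length is a property of
the upstream pipeline, not of the genotype matrix.

$H_t/H_0$ decay regression normalizes per-individual heterozygosity by the
mean of the founder cohort, defined as all individuals carrying the
earliest time label — the natural reading of "initial heterozygosity" when
no founder list is given.  The fit is ordinary least squares with the
two-sided $p$ from the $t$ distribution on $n-2$ degrees of freedom, and a
95% CI on the slope is returned so recovery of a known injected slope can
be asserted.

## Functional variants

`classify_coding_snp()` reconstructs the codon on the coding strand
(reverse-complementing minus-strand genes, including codons split across
exon junctions) and compares translations under the standard genetic code.
NS/S is a **count ratio of heterozygous sites** (non-synonymous = missense
+ stop-gain + stop-loss + start-loss over synonymous), matching the
"non-synonymous/synonymous heterozygosity" framing of per-genome
comparisons — it is deliberately not a per-site-normalized dN/dS.
Loss-of-function for SNPs means stop-gain or start-loss; frameshift LoF
must come from a precomputed indel-effect input, since indel annotation is
out of scope.  Sites in incomplete leading/terminal codons are skipped
with a reported count.

Derived-allele-frequency spectra exclude sites whose outgroup (ancestral)
base matches neither allele, with the exclusion count reported; bins of
width 0.1 partition $(0, 1]$ and per-class fractions sum to 1.

`fisher_exact_2x2()` is an exact hypergeometric enumeration (no
approximation); `lof_enrichment()` applies it per gene, one-sided in each
direction at unadjusted $P < 0.05$ by default, since that mirrors the
stated comparative procedure; a Benjamini–Hochberg mode is provided but
off by default — fidelity first, rigor as an option.  Whether the original
comparison was one- or two-sided, or corrected, is not asserted anywhere.

## Linkage disequilibrium and structure

Two-locus haplotype frequencies come from the standard EM algorithm on
unphased genotypes: only the double heterozygote is phase-ambiguous, the
start point is linkage equilibrium, and iteration stops when no frequency
moves by more than $10^{-8}$ (or 1,000 iterations).  The log-likelihood
trace is returned and tests assert it never decreases.  $r^2 =
D^2/(p_A q_A p_B q_B)$ with $D = f(AB) - p_A p_B$.

A subtlety worth recording: when all four haplotypes segregate, the EM
maximum-likelihood solution necessarily differs from the *realized* gamete
counts of the sample by the double-heterozygote misallocation, whose
scale at $n = 500$ is a few $10^{-3}$.  Exact recovery of phased truth is
only a fair expectation when the population carries at most three
two-locus haplotype types — precisely the situation in a population
descended from a handful of founder chromosomes, which is the regime this
package targets.  The acceptance checks therefore use a founder-limited
(three-haplotype) construction for the exact comparison and keep a looser
all-four-haplotype property test alongside.

LD pre-filters mirror the common Haploview-style parameter set: pairs up
to 300 kb (the "maxdistance 300" convention read as kb, consistent with
half-max distances of tens of kb being measurable), minor-allele frequency
≥ 0.1, genotyped fraction ≥ 0.6, and an exact Hardy–Weinberg test
($p \ge 0.001$) implemented by conditional enumeration.  Distance bins
default to 1 kb up to 10 kb then 5 kb up to the maximum, resolving both a
~1 kb and a ~60 kb half-max regime; pairs are capped per bin by seeded
subsampling.  The half-max distance interpolates linearly between adjacent
bin midpoints and is reported as censored (`> max distance`) when the
curve never reaches half its maximum.

$F_{ST}$ follows Weir & Cockerham (1984): per-locus variance components
$a$ (among subpopulations), $b$ (among individuals within) and $c$ (within
individuals), combined genome-wide as $\sum a / \sum (a+b+c)$ — the
ratio-of-averages form, which no published figure for the four ibis
sub-populations constrains numerically, so only estimator properties
(fixed difference → 1, panmixia → 0, island-model equilibrium) are
asserted.  In the island-model check the package simulates 20 demes;
with $d$ demes the equilibrium is $1/(1 + 4Nm(d/(d-1))^2)$, so a large
$d$ keeps the finite-deme correction small relative to the infinite-island
$1/(1+4Nm)$ yardstick.

## Forensic STR statistics

Match probability uses **observed genotype frequencies**
($PM = \sum g_i^2$, $PD = 1 - PM$, combined $PD = 1 - \prod PM_i$), the
standard forensic power-of-discrimination practice, rather than
HWE-expected genotype frequencies.  Exclusion probability is computed by
**exact enumeration** over (mother genotype, transmitted maternal allele,
true paternal allele, random man) under HWE — several closed-form PE
variants exist and disagree, while enumeration is unambiguous and is
cross-checked against Monte-Carlo trios in the tests.  The paternity index
is the usual likelihood ratio with Mendelian transmission probabilities;
probability of paternity applies a prior of 0.5 (the forensic convention,
configurable).  Major-allele ties break toward the smaller repeat count so
all outputs are deterministic.  Alleles are repeat counts internally;
fragment lengths work identically when a locus carries a length offset.
The W-linked sex marker calls ZW on presence of the insertion allele
(Z length + 31 bp by default), ZZ on a clean Z-only profile, otherwise
inconclusive.

The reported collective discrimination/exclusion figures of published
22-marker panels depend on genotype tables not reproduced here, so the
package reports both the standard combined PD and the per-locus mean
rather than asserting any particular published value.

## The synthetic-data generator

The simulator is forward-in-time Wright–Fisher, not coalescent: founder
pairs, managed pedigrees and STR transmission are pedigree-explicit and
easiest to ground-truth forward.  Parents are drawn uniformly **with
replacement** (canonical monoecious WF sampling), under which expected
heterozygosity decays exactly as $(1 - 1/(2N))$ per generation — the
closed form every drift oracle in the test-suite checks against.  A
no-selfing variant would decay measurably slower at the tiny bottleneck
sizes of interest (at $N = 2$ by roughly a factor of two over ten
generations) and would leave the oracles without a closed form.
Mutation is infinite-sites at rate $\mu L$ per gamete with the ancestral
state known by construction (emulating outgroup-based ancestral-allele
inference without an alignment step); recombination is an optional single
crossover per gamete.  Everything is bit-reproducible under the seed.

For the Watterson-recovery property the founder state is drawn from the
neutral site-frequency spectrum (site count Poisson at its stationary
expectation, frequencies $\propto 1/i$) and then run $N$ further
generations of mutation–drift.  Starting from zero diversity instead would
require a $\gtrsim 10N$-generation burn-in for the sampled diversity to
approach $4N\mu$ (the approach is $1 - e^{-t/2N}$), which is wasteful and,
at shorter burn-ins, biased low.

STR mutation is the symmetric single-step model: each meiosis mutates the
transmitted allele by ±1 repeat with probability $\mu$, reflecting to +1
when a step would reach zero repeats; allele variance then grows as
$\mu t$, the law the tests check.  Multi-step mutations are omitted — the
single-step model is the simplest with a known variance law, and the
mutation hook is one function if heavier tails are ever needed.  Sex
chromosomes are not simulated; the W marker is generated directly from
pedigree sex (dam-to-daughter transmission).

Pedigrees have two modes.  The deterministic managed-expansion mode pools
**all** individuals recorded so far into breeding pairs each season with a
fixed litter size and alternating offspring sexes — with two founder pairs
and two offspring per pair the census doubles each season (4, 4, 8, 16),
a convenient exact fixture.  The random mode breeds only the newest
generation with Poisson litters and Bernoulli sexes, and reports
extinction as an explicit result rather than an error.

The CDS landscape generator packs non-overlapping multi-exon ORFs on both
strands and implants variants whose effect labels are derived from a
self-contained codon table, independent of the classifier's
coordinate machinery — recovering the labels therefore exercises the full
exon/strand/junction mapping rather than a shared code path.  Implants are
placed only in internal codons, so start/stop edge effects are tested
separately with hand-built fixtures.

### What the generator does not emulate

Synthetic data have known ancestral states, clean biallelic sites,
error-free genotypes and exactly-known pedigrees.  Passing tests therefore
demonstrate correctness of the statistics under their model assumptions,
not robustness to genotyping error, allele dropout, null STR alleles,
reference bias or pedigree errors — all of which affect real resequencing
and capillary data.  Selective sweeps are not simulated mechanistically;
a sweep appears in the scan tests as a region of reduced diversity, not as
the product of selection.

## Problem sizes and numerical choices

The test-suite and acceptance script use desk-scale study conditions
chosen once: drift-decay at $N = 50$ over 30 generations with 200
replicates and a 3-standard-error band; Watterson recovery at $N = 100$,
$\mu = 10^{-5}$, $L = 10^4$ over 50 replicates (15% band); EM truth
comparisons at $n = 500$ individuals; the island model with 20 demes of
$N = 100$ at $m = 0.01$ for 300 generations, 100 loci, 30 samples per
deme (20% band); forensic ranking with 22 loci of five equifrequent
alleles, 100 replicates against 100 random non-fathers; and an injected
$H_t/H_0$ decline of $-0.017$/year with Gaussian noise (sd 0.05) across
105 individuals over 21 years, the scale of a managed-recovery monitoring
dataset.  Degenerate inputs error loudly and early: monomorphic loci for
$r^2$, $\sigma_{H_p} = 0$, empty founder cohorts, single subpopulations,
all-missing STR loci, mother–child Mendelian incompatibilities (named by
locus).

## Known limitations

* The VCF subset is minimal by design: biallelic SNPs with GT (+ optional
  AD/AA); no phased ploidy > 2, symbolic alleles, BCF or tabix.
* LoF classification for SNPs cannot see frameshifts; supply indel effects
  externally.
* `em_haplotype_freqs()` is two-locus only; no multi-locus phasing and no
  D′-based block structure.
* The W-marker model assumes the insertion allele is fully penetrant and
  W-exclusive; real marker dropout would need the `inconclusive` path.
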