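Package: ibispop
Title: Conservation Population Genomics for Bottlenecked Bird Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-diversity, linkage and forensic-marker statistics for
    severely bottlenecked populations such as the recovered crested ibis.
    Implements per-genome heterozygosity and Watterson's theta, the windowed
    pooled-heterozygosity (Hp/ZHp) fixation scan with a normal-quantile
    threshold, heterozygosity-decay (Ht/H0) regression, coding-variant
    classification with NS/S ratios and derived-allele-frequency spectra,
    per-gene loss-of-function enrichment by Fisher's exact test, EM-based
    two-locus r2 linkage disequilibrium with decay curves and half-maximum
    distances, Weir-Cockerham FST, and a forensic STR toolkit (discrimination
    power, exclusion probability, paternity index, W-linked sex calling).
    A forward-in-time Wright-Fisher simulator with stepwise-mutation STR
    loci, multi-generation pedigrees and effect-labelled coding variants
    supplies fully synthetic inputs with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    vcfR,
    seqinr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
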