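test_that("codon classification covers the canonical substitution types", {
  # ATG GCT ATG TGG CTG TAA : start, A, M, W, L, stop
  seqs <- "ATGGCTATGTGGCTGTAA"
  cds <- cds_model("g1", "chr1", "+", cbind(0, 18))
  # internal ATG -> ATA at codon position 3: M -> I missense
  eff <- classify_coding_snp(cds, seqs, 9, "G", "A")
  expect_equal(eff$effect, "missense")
  expect_equal(c(eff$ref_aa, eff$alt_aa), c("M", "I"))
  # CTG -> CTA: synonymous leucine
  eff <- classify_coding_snp(cds, seqs, 15, "G", "A")
  expect_equal(eff$effect, "synonymous")
  expect_false(eff$lof)
  # TGG -> TGA: stop gain, LoF
  eff <- classify_coding_snp(cds, seqs, 12, "G", "A")
  expect_equal(eff$effect, "stop_gain")
  expect_true(eff$lof)
  # initiator ATG disrupted: start loss, LoF
  eff <- classify_coding_snp(cds, seqs, 3, "G", "A")
  expect_equal(eff$effect, "start_loss")
  expect_true(eff$lof)
  # stop codon reverted: stop loss
  eff <- classify_coding_snp(cds, seqs, 17, "A", "C")
  expect_equal(eff$effect, "stop_loss")
  expect_error(classify_coding_snp(cds, seqs, 25, "A", "C"), "outside")
  expect_error(classify_coding_snp(cds, seqs, 9, "C", "A"),
               "reference mismatch")
})

test_that("classification agrees with whole-CDS translation oracle on random models", {
  # randomized multi-exon genes on both strands, codons split across exons
  for (seed in 1:4) {
    ls <- generate_cds_landscape(genome_length = 3e4, n_genes = 5,
                                 n_syn = 25, ns_ratio = 0.6, seed = seed)
    cds_by_id <- setNames(ls$cds_list,
                          vapply(ls$cds_list, `[[`, character(1), "gene_id"))
    chrom_seq <- ls$genome[["chr1"]]
    chars <- strsplit(chrom_seq, "")[[1]]
    translate_cds <- function(cds, chars) {
      pieces <- unlist(lapply(seq_len(nrow(cds$exons)), function(e)
        chars[(cds$exons[e, 1] + 1):cds$exons[e, 2]]))
      if (cds$strand == "-")
        pieces <- rev(c(A = "T", C = "G", G = "C", T = "A")[pieces])
      paste(seqinr::translate(pieces), collapse = "")
    }
    for (k in seq_len(nrow(ls$variants))) {
      v <- ls$variants[k, ]
      cds <- cds_by_id[[v$gene_id]]
      eff <- classify_coding_snp(cds, chrom_seq, v$pos, v$ref, v$alt)
      prot_ref <- translate_cds(cds, chars)
      chars_alt <- chars
      chars_alt[v$pos] <- v$alt
      prot_alt <- translate_cds(cds, chars_alt)
      oracle <-
        if (prot_ref == prot_alt) "synonymous"
        else if (substr(prot_alt, eff$codon_index, eff$codon_index) == "*")
          "stop_gain"
        else "missense"
      expect_equal(eff$effect, oracle)
      expect_equal(eff$effect, v$true_effect)
    }
  }
})

test_that("NS/S het ratio counts non-synonymous over synonymous", {
  effs <- c(rep("missense", 60), rep("stop_gain", 9), rep("synonymous", 100))
  expect_equal(ns_s_ratio(effs), 0.69)
  expect_equal(ns_s_ratio(rep("synonymous", 10)), 0)
  expect_equal(ns_s_ratio(c("missense", "synonymous")), 1)
  expect_true(is.na(ns_s_ratio(c("missense"))))
})

test_that("derived-allele spectrum bins and normalizes per class", {
  # 9 diploids, derived = alt (anc = ref); 2 derived copies of 18 -> (0.1,0.2]
  gt <- matrix(0L, 3, 9)
  gt[1, 1] <- 2L              # freq 2/18
  gt[2, ] <- 2L               # fixed derived -> last bin
  gt[3, 1:3] <- 1L            # freq 3/18
  gm <- genotype_matrix(rep("chr1", 3), c(10L, 20L, 30L),
                        rep("A", 3), rep("G", 3), gt,
                        sprintf("s%d", 1:9), anc = rep("A", 3))
  sp <- daf_spectrum(gm, class = c("NS", "NS", "S"))
  ns <- sp[sp$class == "NS", ]
  expect_equal(ns$fraction[ns$bin_low == 0.1], 0.5)
  expect_equal(ns$fraction[ns$bin_low == 0.9], 0.5)
  s <- sp[sp$class == "S", ]
  expect_equal(s$fraction[s$bin_low == 0.1], 1)
  for (cl in unique(sp$class))
    expect_equal(sum(sp$fraction[sp$class == cl]), 1, tolerance = 1e-12)
  gm_no_anc <- genotype_matrix("chr1", 10L, "A", "G", matrix(1L, 1, 1), "s1")
  expect_error(daf_spectrum(gm_no_anc), "ancestral")
})

test_that("NS and S spectra are exchangeable when effects ignore frequency", {
  set.seed(21)
  gm <- random_gm(n_sites = 300, n_samples = 10, seed = 21,
                  missing_rate = 0, with_anc = TRUE)
  cls <- sample(c("NS", "S"), 300, replace = TRUE)
  sp <- daf_spectrum(gm, class = cls)
  # chi-square-style distance between the two spectra vs its permutation null
  dist_of <- function(sp) {
    a <- sp$fraction[sp$class == "NS"]
    b <- sp$fraction[sp$class == "S"]
    sum((a - b)^2)
  }
  obs <- dist_of(sp)
  null <- replicate(200, dist_of(daf_spectrum(gm, class = sample(cls))))
  expect_gt(mean(null >= obs), 0.01)
})

test_that("Fisher exact test matches enumeration and reference implementation", {
  # the 3-of-8 vs 0-of-15 inactivation pattern
  f <- fisher_exact_2x2(3, 5, 0, 15)
  expect_equal(f$p_greater, 56 / 1771, tolerance = 1e-12)
  expect_lt(f$p_greater, 0.05)
  expect_equal(fisher_exact_2x2(0, 8, 0, 15)$p_greater, 1)
  expect_equal(fisher_exact_2x2(4, 4, 4, 4)$p_two, 1)
  # independent closed-form enumeration oracle over margins up to 30
  set.seed(13)
  for (rep in 1:40) {
    m <- sample(0:15, 1); n <- sample(1:15, 1); k <- sample(0:(m + n), 1)
    a_range <- max(0, k - n):min(k, m)
    a <- a_range[sample.int(length(a_range), 1)]
    b <- m - a; cc <- k - a; d <- n - cc
    f <- fisher_exact_2x2(a, b, cc, d)
    x <- max(0, k - n):min(k, m)
    probs <- choose(m, x) * choose(n, k - x) / choose(m + n, k)
    expect_equal(f$p_greater, sum(probs[x >= a]), tolerance = 1e-10)
    expect_equal(f$p_less, sum(probs[x <= a]), tolerance = 1e-10)
    expect_equal(f$p_two,
                 stats::fisher.test(matrix(c(a, cc, b, d), 2))$p.value,
                 tolerance = 1e-7)
  }
})

test_that("LoF enrichment flags extreme genes and controls false positives", {
  lof <- rbind(all_ev = c(rep(1, 8), rep(0, 15)),
               nobody = rep(0, 23),
               all_lc = c(rep(0, 8), rep(1, 15)))
  groups <- rep(c("EV", "LC"), c(8, 15))
  res <- lof_enrichment(lof, groups)
  expect_true("all_ev" %in% res$enriched$EV)
  expect_false("nobody" %in% unlist(res$enriched))
  expect_true("all_lc" %in% res$enriched$LC)
  expect_error(lof_enrichment(lof[, 1:8, drop = FALSE], rep("EV", 8)),
               "two groups")
  # null: equal inactivation probability in both groups
  set.seed(31)
  null_lof <- matrix(rbinom(1000 * 23, 1, 0.2), 1000, 23,
                     dimnames = list(sprintf("g%04d", 1:1000), NULL))
  res0 <- lof_enrichment(null_lof, groups)
  expect_lte(length(res0$enriched$EV) / 1000, 0.05)
  expect_lte(length(res0$enriched$LC) / 1000, 0.05)
})
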