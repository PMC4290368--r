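test_that("perfect-STR scanner: basic runs, primitivity, N breaks", {
  res <- scan_perfect_strs("ACACACAC", min_total_length = 8)
  expect_equal(nrow(res), 1)
  expect_equal(res$unit_size, 2)
  expect_equal(res$n_repeats, 4)
  expect_equal(c(res$start, res$end), c(0, 8))

  expect_equal(nrow(scan_perfect_strs("ACGTACGA", min_total_length = 8)), 0)
  # ATATATAT is a 2-bp repeat, never reported at unit 4
  res2 <- scan_perfect_strs("ATATATAT", min_total_length = 8)
  expect_equal(res2$unit_size, 2)
  # an N splits the run below the length threshold
  expect_equal(nrow(scan_perfect_strs("ACACNACAC", min_total_length = 8)), 0)
})

test_that("scanner equals the brute-force oracle on random sequences", {
  for (seed in 1:3) {
    s <- random_dna(5000, seed = seed, with_n = TRUE)
    # seed repeats so the sequence is not repeat-free
    s <- paste0(s, "GATAGATAGATAGATA", substr(s, 1, 500),
                "CCCGCCCGCCCG", "TTATTTATTTATT")
    expect_equal(scan_perfect_strs(s, min_total_length = 8),
                 brute_force_strs(s, min_total_length = 8))
  }
})

test_that("locus summary: frequencies, ties, size differences, He", {
  tbl <- str_genotype_table(c("i1", "i2"), "L1", 4,
                            matrix(c(10, 10), 2), matrix(c(10, 12), 2))
  sm <- str_locus_summary(tbl, "L1")
  expect_equal(unname(sm$allele_freqs), c(0.75, 0.25))
  expect_equal(sm$major, 10)
  expect_equal(sm$minors, 12)
  expect_equal(sm$size_differences_bp, 8)  # 2 repeats * 4 bp
  expect_equal(sm$expected_heterozygosity, 0.375)

  mono <- str_genotype_table("i1", "L1", 4, matrix(9), matrix(9))
  sm2 <- str_locus_summary(mono, "L1")
  expect_equal(sm2$expected_heterozygosity, 0)
  expect_equal(sm2$n_alleles, 1)

  # equal frequencies: He = 0.5, tie breaks to the smaller repeat count
  even <- str_genotype_table("i1", "L1", 2, matrix(11), matrix(8))
  sm3 <- str_locus_summary(even, "L1")
  expect_equal(sm3$expected_heterozygosity, 0.5)
  expect_equal(sm3$major, 8)

  allmiss <- str_genotype_table("i1", "L1", 4, matrix(NA_real_), matrix(NA_real_))
  expect_error(str_locus_summary(allmiss, "L1"), "all genotypes missing")
})

test_that("polymorphic fraction stratifies by unit size and tracks mutation rate", {
  mk <- function(n_alleles, unit) {
    tbl <- str_genotype_table(sprintf("i%d", 1:4), "L", unit,
                              matrix(rep(seq_len(n_alleles), length.out = 4)) + 7,
                              matrix(rep(seq_len(n_alleles), length.out = 4)) + 7)
    str_locus_summary(tbl, "L")
  }
  sums <- list(mk(1, 2), mk(4, 2), mk(1, 4))
  pf <- polymorphic_fraction(sums, min_alleles = 4)
  expect_equal(pf$fraction[pf$unit_size == 2], 0.5)
  expect_equal(pf$fraction[pf$unit_size == 4], 0)
  expect_equal(polymorphic_fraction(list(mk(1, 2)), 4)$fraction, 0)
  expect_equal(polymorphic_fraction(list(mk(4, 2)), 4)$fraction, 1)

  # higher SMM rate -> more polymorphic loci
  ps <- simulate_pedigree(4, 5, offspring_per_pair = 2, seed = 2)
  frac_at <- function(mu, seed) {
    tbl <- simulate_str_smm(ps, n_loci = 60, mu = mu,
                            founder_alleles = 10, seed = seed)
    sums <- lapply(tbl$locus_ids, function(lc) str_locus_summary(tbl, lc))
    mean(vapply(sums, `[[`, numeric(1), "n_alleles") >= 3)
  }
  expect_gt(frac_at(0.08, 5), frac_at(0.005, 5))
})

test_that("match probability and combined discrimination power", {
  # four equally frequent genotypes
  tbl <- str_genotype_table(sprintf("i%d", 1:4), c("L1", "L2"), c(4, 4),
                            matrix(c(8, 9, 10, 11,   8, 8, 9, 9), 4),
                            matrix(c(8, 9, 10, 11,   8, 8, 9, 9), 4))
  mp <- match_probability(tbl, "L1")
  expect_equal(mp$pm, 0.25)
  expect_equal(mp$pd, 0.75)
  # single shared genotype
  tbl1 <- str_genotype_table(c("a", "b"), "L1", 4, matrix(c(8, 8), 2),
                             matrix(c(8, 8), 2))
  expect_equal(match_probability(tbl1, "L1")$pm, 1)
  expect_equal(match_probability(tbl1, "L1")$pd, 0)
  # combined PD over two loci with PM 0.25 and 0.5
  panel <- forensic_panel(tbl)
  expect_equal(panel$per_locus$pm, c(0.25, 0.5))
  expect_equal(panel$combined_pd, 1 - 0.25 * 0.5)
  expect_equal(panel$per_locus$pd + panel$per_locus$pm, c(1, 1))
})

test_that("exclusion probability: enumeration, closed form, monotonicity", {
  expect_equal(exclusion_probability(c(a = 1)), 0)
  # two-allele closed form p*q*(1 - p*q)
  for (p in c(0.5, 0.2, 0.35)) {
    q <- 1 - p
    expect_equal(exclusion_probability(c(a = p, b = q)), p * q * (1 - p * q),
                 tolerance = 1e-12)
  }
  # Monte-Carlo oracle for a 4-allele locus
  fr <- c(a = 0.4, b = 0.3, c = 0.2, d = 0.1)
  pe <- exclusion_probability(fr)
  set.seed(77)
  nmc <- 40000
  draw <- function(n) sample(names(fr), n, TRUE, prob = fr)
  mom <- cbind(draw(nmc), draw(nmc))
  dadal <- draw(nmc)
  manal <- cbind(draw(nmc), draw(nmc))
  excl <- vapply(seq_len(nmc), function(i) {
    m <- mom[i, ]
    child <- c(m[sample.int(2, 1)], dadal[i])
    cand <- unique(c(if (child[2] %in% m) child[1],
                     if (child[1] %in% m) child[2]))
    !any(manal[i, ] %in% cand)
  }, logical(1))
  se <- sqrt(pe * (1 - pe) / nmc)
  expect_lt(abs(mean(excl) - pe), 3 * se + 1e-9)
  # combined PE never decreases when a locus is added
  pes <- c(0.3, 0.5, 0.1)
  comb <- 1 - cumprod(1 - pes)
  expect_true(all(diff(comb) >= 0))
})

test_that("paternity index: obligate allele cases and probability conversion", {
  fr <- c("8" = 0.2, "9" = 0.5, "10" = 0.3)
  # father homozygous for the obligate paternal allele -> PI = 1/p
  expect_equal(paternity_index(c(9, 9), c(9, 8), c(8, 8), fr), 1 / 0.2)
  # father lacks the obligate allele -> PI 0
  expect_equal(paternity_index(c(9, 9), c(9, 8), c(10, 10), fr), 0)
  expect_equal(probability_of_paternity(0), 0)
  # mother-child incompatibility errors with the locus name
  expect_error(paternity_index(c(10, 10), c(8, 9), c(8, 8), fr, locus = "Lx"),
               "Lx")
  # the forensic reporting scale: combined PI of 33332 gives W of 99.997%
  expect_equal(probability_of_paternity(33332), 33332 / 33333,
               tolerance = 1e-9)
  expect_equal(round(100 * probability_of_paternity(33332), 3), 99.997)
})

test_that("averaging PI over random HWE men equals 1", {
  fr <- c("8" = 0.25, "9" = 0.4, "10" = 0.2, "11" = 0.15)
  set.seed(41)
  m <- c(9, 10)
  child <- c(9, 8)  # paternal allele 8
  nmc <- 20000
  men1 <- sample(names(fr), nmc, TRUE, prob = fr)
  men2 <- sample(names(fr), nmc, TRUE, prob = fr)
  pis <- vapply(seq_len(nmc), function(i)
    paternity_index(m, child, as.numeric(c(men1[i], men2[i])), fr),
    numeric(1))
  expect_lt(abs(mean(pis) - 1), 3 * sd(pis) / sqrt(nmc) + 0.01)
})

test_that("trio paternity on a simulated pedigree favours the true father", {
  ps <- simulate_pedigree(3, 2, offspring_per_pair = 2, seed = 6)
  tbl <- simulate_str_smm(ps, n_loci = 22, mu = 0, founder_alleles = 6:14,
                          seed = 7)
  kid <- ps$ped[!is.na(ps$ped$sire_id), ][1, ]
  res <- trio_paternity(tbl, kid$dam_id, kid$individual_id, kid$sire_id)
  expect_gte(res$combined_pi, 1)
  expect_gt(res$w, 0.5)
  expect_equal(nrow(res$per_locus), 22)
})

test_that("W-marker sex calls", {
  expect_equal(sex_call(c(180, 211), z_length = 180), "ZW")
  expect_equal(sex_call(c(180, 180), z_length = 180), "ZZ")
  expect_equal(sex_call(c(NA, NA), z_length = 180), "inconclusive")
  expect_equal(sex_call(c(150, 150), z_length = 180), "inconclusive")
  ps <- simulate_pedigree(2, 2, seed = 3)
  wm <- simulate_w_marker(ps)
  calls <- vapply(seq_len(nrow(wm)), function(i)
    sex_call(c(wm$a1[i], wm$a2[i]), z_length = 180), character(1))
  expect_equal(calls, wm$true_sex)
})
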