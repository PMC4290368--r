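test_that("EM equals direct gamete counting without double heterozygotes", {
  # genotypes chosen so no individual is het at both loci
  ga <- c(0, 0, 2, 2, 1, 0)
  gb <- c(0, 1, 2, 0, 0, 2)
  em <- em_haplotype_freqs(ga, gb)
  # direct count: each individual contributes two unambiguous gametes
  expect_equal(sum(em$freqs), 1, tolerance = 1e-12)
  # gametes: AB x4 (s1 twice, s2, s5), Ab x3, aB x3, ab x2
  expect_equal(unname(em$freqs["AB"]), 4 / 12, tolerance = 1e-9)
  expect_equal(unname(em$freqs["ab"]), 2 / 12, tolerance = 1e-9)
  expect_lte(em$n_iter, 2)
})

test_that("complete LD and equilibrium constructions give r2 = 1 and 0", {
  # only coupling gametes AB/ab
  pop <- draw_two_locus_pop(300, c(AB = 0.6, Ab = 0, aB = 0, ab = 0.4),
                            seed = 2)
  em <- em_haplotype_freqs(pop$ga, pop$gb)
  expect_equal(unname(em$freqs[["AB"]] + em$freqs[["ab"]]), 1,
               tolerance = 1e-9)
  expect_equal(r_squared(em)$r2, 1, tolerance = 1e-9)
  # exact linkage equilibrium frequencies
  pA <- 0.7; pB <- 0.4
  f_eq <- c(AB = pA * pB, Ab = pA * (1 - pB), aB = (1 - pA) * pB,
            ab = (1 - pA) * (1 - pB))
  expect_equal(r_squared(f_eq)$r2, 0, tolerance = 1e-12)
  expect_error(em_haplotype_freqs(rep(0, 10), c(0, 1, rep(2, 8))),
               "monomorphic")
})

test_that("r2 hand-arithmetic oracle", {
  res <- r_squared(c(AB = 0.4, Ab = 0.1, aB = 0.1, ab = 0.4))
  expect_equal(res$D, 0.15, tolerance = 1e-12)
  expect_equal(res$r2, 0.36, tolerance = 1e-12)
})

test_that("EM log-likelihood is non-decreasing and matches phased truth", {
  for (seed in 1:5) {
    set.seed(seed)
    f <- as.numeric(gtools_like_dirichlet <- {
      x <- rgamma(4, 1); x / sum(x)
    })
    names(f) <- c("AB", "Ab", "aB", "ab")
    pop <- draw_two_locus_pop(500, f, seed = seed + 100)
    em <- tryCatch(em_haplotype_freqs(pop$ga, pop$gb),
                   error = function(e) NULL)  # rare monomorphic draws
    if (is.null(em)) next
    expect_true(all(diff(em$loglik) > -1e-8))
    expect_equal(sum(em$freqs), 1, tolerance = 1e-9)
    # with all four haplotypes present the double-het phase is ambiguous;
    # the MLE still tracks the realized gamete frequencies closely
    expect_lt(max(abs(em$freqs - as.numeric(pop$realized))), 0.02)
  }
})

test_that("exact HWE test matches a permutation oracle", {
  # null distribution of heterozygote counts by shuffling the allele pool
  set.seed(17)
  n_aa <- 18; n_ab <- 4; n_bb <- 3   # het deficit
  n <- n_aa + n_ab + n_bb
  pool <- rep(0:1, c(2 * n_aa + n_ab, n_ab + 2 * n_bb))
  hets <- replicate(4000, {
    x <- matrix(sample(pool), ncol = 2)
    sum(x[, 1] != x[, 2])
  })
  p_exact <- hwe_exact_p(n_aa, n_ab, n_bb)
  probs <- table(factor(hets, 0:n)) / length(hets)
  obs_p <- probs[as.character(n_ab)]
  p_sim <- sum(probs[probs <= obs_p + 1e-9])
  expect_equal(p_exact, p_sim, tolerance = 0.05)
  expect_equal(hwe_exact_p(10, 0, 0), 1)
})

test_that("LD curve respects all pair filters", {
  set.seed(8)
  n <- 40
  good <- function() {
    g <- sample(0:2, n, TRUE, prob = c(0.49, 0.42, 0.09))
    g
  }
  gt <- rbind(good(), good(), good())
  # adversarial sites: low MAF, heavy missingness, extreme HWE violation
  low_maf <- c(rep(0L, n - 1), 1L)
  missing <- c(rep(NA_integer_, 30), sample(0:2, 10, TRUE))
  hwe_bad <- rep(c(0L, 2L), n / 2)   # no hets at intermediate frequency
  gt <- rbind(gt, low_maf, missing, hwe_bad)
  gm <- genotype_matrix(rep("chr1", 6), c(1e3, 2e3, 3e3, 4e3, 5e3, 6e3),
                        rep("A", 6), rep("G", 6), gt, sprintf("s%d", 1:n))
  cfg <- ld_config(max_distance = 1e5)
  keep <- ibispop:::ld_site_filter(gm, cfg)
  expect_equal(keep, c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  curve <- ld_decay_curve(gm, cfg)
  expect_equal(sum(curve$n_pairs), 3)  # choose(3, 2)
  # filters that exclude everything raise an error
  expect_error(ld_decay_curve(gm, ld_config(min_maf = 0.49)), "no site pairs")
})

test_that("single-pair curve equals that pair's r2; distance cap respected", {
  set.seed(12)
  h <- sample(c("AB", "ab", "Ab"), 120, TRUE, prob = c(0.5, 0.3, 0.2))
  h2 <- sample(c("AB", "ab", "Ab"), 120, TRUE, prob = c(0.5, 0.3, 0.2))
  ga <- (substr(h, 1, 1) == "a") + (substr(h2, 1, 1) == "a")
  gb <- (substr(h, 2, 2) == "b") + (substr(h2, 2, 2) == "b")
  gm <- genotype_matrix(rep("chr1", 2), c(1000L, 3500L), c("A", "C"),
                        c("G", "T"), rbind(ga, gb), sprintf("s%d", 1:120))
  cfg <- ld_config(hwe_p_cutoff = 0)
  curve <- ld_decay_curve(gm, cfg)
  em <- em_haplotype_freqs(ga, gb)
  in_bin <- which(curve$n_pairs == 1)
  expect_length(in_bin, 1)
  expect_equal(curve$mean_r2[in_bin], r_squared(em)$r2)
  expect_true(curve$bin_low[in_bin] < 2500 & curve$bin_high[in_bin] >= 2500)
  # out-of-range pair excluded
  gm2 <- genotype_matrix(rep("chr1", 2), c(1000L, 900000L), c("A", "C"),
                         c("G", "T"), rbind(ga, gb), sprintf("s%d", 1:120))
  expect_error(ld_decay_curve(gm2, cfg), "no site pairs")
})

test_that("r2 decays with distance in a recombining population", {
  cfg <- demography_config(data.frame(N = 60, duration = 60), mu = 0,
                           L = 1e6, recomb_rate = 5e-8,
                           init_sites = 300, init_freq = 0.5,
                           sample_times = 60, sample_sizes = 50, seed = 99)
  sim <- simulate_wright_fisher(cfg)
  gm <- sim$samples[[1]]$gm
  set.seed(100)
  curve <- ld_decay_curve(gm, ld_config(max_distance = 9e5, hwe_p_cutoff = 0,
                                        max_pairs_per_bin = 300),
                          breaks = seq(0, 9e5, by = 1e5))
  ok <- curve$n_pairs > 20
  expect_gt(sum(ok), 3)
  expect_lt(cor(curve$mid[ok], curve$mean_r2[ok], method = "spearman"), 0)
})

test_that("half-max distance: exact hit, interpolation, censoring", {
  curve <- data.frame(mid = c(0, 10000, 20000), mean_r2 = c(1, 0.5, 0.25))
  hm <- half_max_distance(curve)
  expect_equal(hm$distance, 10000)
  expect_false(hm$censored)
  hm2 <- half_max_distance(data.frame(mid = c(0, 10000, 20000),
                                      mean_r2 = c(0.8, 0.6, 0.2)))
  expect_equal(hm2$distance, 15000)
  flat <- half_max_distance(data.frame(mid = c(0, 10000), mean_r2 = c(0.4, 0.4)))
  expect_true(flat$censored)
  expect_error(half_max_distance(data.frame(mid = numeric(),
                                            mean_r2 = numeric())), "empty")
})

test_that("Weir-Cockerham FST: fixed difference, panmixia, duplication invariance", {
  gm_fix <- genotype_matrix("chr1", 1L, "A", "G",
                            matrix(c(0L, 0L, 0L, 2L, 2L, 2L), 1),
                            sprintf("s%d", 1:6))
  expect_equal(weir_cockerham_fst(gm_fix, rep(c("p1", "p2"), each = 3))$theta_global, 1)
  expect_error(weir_cockerham_fst(gm_fix, rep("p1", 6)), ">= 2")

  # identical genotype proportions in both subpopulations
  block <- c(rep(0L, 20), rep(1L, 40), rep(2L, 20))
  gm_same <- genotype_matrix("chr1", 1L, "A", "G",
                             matrix(c(block, block), 1),
                             sprintf("s%d", 1:160))
  expect_lt(abs(weir_cockerham_fst(gm_same,
                                   rep(c("p1", "p2"), each = 80))$theta_global),
            0.02)

  set.seed(4)
  gm <- random_gm(40, 12, seed = 44, missing_rate = 0.05)
  pops <- rep(c("a", "b", "c"), each = 4)
  f1 <- weir_cockerham_fst(gm, pops)
  gm_dup <- genotype_matrix(gm$chrom, gm$pos, gm$ref, gm$alt,
                            cbind(gm$gt, gm$gt),
                            c(gm$sample_ids, paste0(gm$sample_ids, "_dup")))
  f2 <- weir_cockerham_fst(gm_dup, c(pops, pops))
  expect_equal(f2$theta_global, f1$theta_global, tolerance = 0.15)
})
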