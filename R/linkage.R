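#' EM haplotype-frequency estimation for two unphased loci
#'
#' Maximum-likelihood two-locus haplotype frequencies from unphased diploid
#' genotypes (the standard EM used for r2 on population resequencing data).
#' Only the double-heterozygote class has ambiguous phase; starting from
#' linkage equilibrium (product of allele frequencies), each E step splits
#' the double heterozygotes between the coupling (AB/ab) and repulsion
#' (Ab/aB) resolutions in proportion to the current frequency products.
#' Convergence: maximum frequency change below `tol` or `max_iter`
#' iterations.  The log-likelihood is non-decreasing across iterations and
#' is returned for inspection.
#'
#' @param ga,gb integer vectors of alt-allele dosages (0/1/2, `NA` missing)
#'   at the two loci; individuals missing either genotype are dropped.
#' @param tol convergence tolerance on frequencies (default 1e-8).
#' @param max_iter iteration cap (default 1000).
#' @return List of class `em_haplotypes`: `freqs` (named `AB`, `Ab`, `aB`,
#'   `ab`, where `A`/`B` denote the reference alleles), `loglik` (trace),
#'   `n_iter`, `n` (individuals used).
#' @export
em_haplotype_freqs <- function(ga, gb, tol = 1e-8, max_iter = 1000L) {
  keep <- !is.na(ga) & !is.na(gb)
  ga <- ga[keep]; gb <- gb[keep]
  n <- length(ga)
  if (n < 1) stop("no individual genotyped at both loci", call. = FALSE)
  if (length(unique(ga)) == 1 || length(unique(gb)) == 1)
    stop("monomorphic locus: haplotype frequencies unidentifiable",
         call. = FALSE)
  # genotype class counts; dosage counts the alt allele, A/B = ref
  cnt <- matrix(tabulate(3L * ga + gb + 1L, 9L), 3, 3, byrow = TRUE,
                dimnames = list(0:2, 0:2))
  pA <- 1 - mean(ga) / 2
  pB <- 1 - mean(gb) / 2
  f <- c(AB = pA * pB, Ab = pA * (1 - pB), aB = (1 - pA) * pB,
         ab = (1 - pA) * (1 - pB))
  n_dh <- cnt["1", "1"]
  # unambiguous haplotype contributions (counts of each haplotype over 2n
  # gametes, excluding the double heterozygotes)
  base <- c(
    AB = 2 * cnt["0", "0"] + cnt["0", "1"] + cnt["1", "0"],
    Ab = 2 * cnt["0", "2"] + cnt["0", "1"] + cnt["1", "2"],
    aB = 2 * cnt["2", "0"] + cnt["1", "0"] + cnt["2", "1"],
    ab = 2 * cnt["2", "2"] + cnt["2", "1"] + cnt["1", "2"])
  loglik <- function(f) {
    probs <- c(f["AB"]^2, 2 * f["AB"] * f["Ab"], f["Ab"]^2,
               2 * f["AB"] * f["aB"],
               2 * (f["AB"] * f["ab"] + f["Ab"] * f["aB"]),
               2 * f["Ab"] * f["ab"],
               f["aB"]^2, 2 * f["aB"] * f["ab"], f["ab"]^2)
    obs <- c(cnt["0", "0"], cnt["0", "1"], cnt["0", "2"],
             cnt["1", "0"], cnt["1", "1"], cnt["1", "2"],
             cnt["2", "0"], cnt["2", "1"], cnt["2", "2"])
    sum(obs[probs > 0] * log(probs[probs > 0]))
  }
  ll <- loglik(f)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    denom <- f["AB"] * f["ab"] + f["Ab"] * f["aB"]
    w <- if (denom > 0) f["AB"] * f["ab"] / denom else 0.5
    exp_counts <- base + n_dh * c(AB = w, Ab = 1 - w, aB = 1 - w, ab = w)
    f_new <- exp_counts / (2 * n)
    delta <- max(abs(f_new - f))
    f <- f_new
    ll <- c(ll, loglik(f))
    if (delta < tol || iter >= max_iter) break
  }
  structure(list(freqs = f, loglik = unname(ll), n_iter = iter, n = n),
            class = "em_haplotypes")
}

#' r-squared from two-locus haplotype frequencies
#'
#' `r2 = D^2 / (pA qA pB qB)` with `D = f(AB) - pA pB`.  Returns `NA` when
#' either locus is monomorphic under the supplied frequencies (zero
#' denominator; the pair is skipped by [ld_decay_curve()]).
#'
#' @param hap_freqs numeric vector with names `AB`, `Ab`, `aB`, `ab`
#'   (or an `em_haplotypes` object).
#' @return List with `r2`, `D`, `pA`, `pB`.
#' @export
r_squared <- function(hap_freqs) {
  if (inherits(hap_freqs, "em_haplotypes")) hap_freqs <- hap_freqs$freqs
  f <- hap_freqs[c("AB", "Ab", "aB", "ab")]
  pA <- f[["AB"]] + f[["Ab"]]
  pB <- f[["AB"]] + f[["aB"]]
  D <- f[["AB"]] - pA * pB
  den <- pA * (1 - pA) * pB * (1 - pB)
  list(r2 = if (den > 0) D^2 / den else NA_real_, D = D, pA = pA, pB = pB)
}

#' Exact Hardy-Weinberg test for one biallelic locus
#'
#' Exact conditional test: given the minor-allele count, the probability of
#' each possible heterozygote count is computed by enumeration and the
#' p-value sums the probabilities of outcomes no more probable than the
#' observed one (the convention used by LD-analysis pre-filters).
#'
#' @param n_aa,n_ab,n_bb genotype counts (hom, het, hom).
#' @return Exact two-sided p-value.
#' @export
hwe_exact_p <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  n_rare <- 2 * min(n_aa, n_bb) + n_ab  # minor allele copies
  if (n == 0 || n_rare == 0) return(1)
  hets <- seq(n_rare %% 2, n_rare, by = 2)
  logp <- vapply(hets, function(h) {
    hom_r <- (n_rare - h) / 2
    hom_c <- n - h - hom_r
    lgamma(n + 1) - lgamma(h + 1) - lgamma(hom_r + 1) - lgamma(hom_c + 1) +
      h * log(2) + lgamma(n_rare + 1) + lgamma(2 * n - n_rare + 1) -
      lgamma(2 * n + 1)
  }, numeric(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[hets == n_ab]
  sum(p[p <= obs * (1 + 1e-7)])
}

#' LD analysis configuration
#'
#' Defaults mirror the common Haploview-style parameter set for population
#' resequencing panels: pairs up to 300 kb apart, minor-allele frequency at
#' least 0.1, at least 60% of individuals genotyped, and an exact
#' Hardy-Weinberg p-value of at least 0.001.
#'
#' @param max_distance maximum pair distance in bp.
#' @param min_maf minimum minor-allele frequency.
#' @param min_genotyped_fraction minimum fraction of non-missing genotypes.
#' @param hwe_p_cutoff minimum exact-HWE p-value.
#' @param max_pairs_per_bin random-subsample cap on pairs per distance bin.
#' @return List of class `ld_config`.
#' @export
ld_config <- function(max_distance = 3e5, min_maf = 0.1,
                      min_genotyped_fraction = 0.6, hwe_p_cutoff = 0.001,
                      max_pairs_per_bin = 1e5) {
  stopifnot(max_distance > 0, min_maf >= 0, min_maf < 0.5,
            min_genotyped_fraction >= 0, min_genotyped_fraction <= 1,
            hwe_p_cutoff >= 0, hwe_p_cutoff <= 1)
  structure(list(max_distance = max_distance, min_maf = min_maf,
                 min_genotyped_fraction = min_genotyped_fraction,
                 hwe_p_cutoff = hwe_p_cutoff,
                 max_pairs_per_bin = max_pairs_per_bin),
            class = "ld_config")
}

#' Default LD distance bins
#'
#' 1-kb bins to 10 kb, then 5-kb bins to `max_distance` — fine enough to
#' resolve a ~1 kb half-max decay and wide enough to cover a ~60 kb one.
#'
#' @param max_distance largest distance covered (bp).
#' @return Numeric vector of bin breaks starting at 0.
#' @export
ld_distance_breaks <- function(max_distance = 3e5) {
  c(seq(0, 10e3, by = 1e3), seq(15e3, max_distance, by = 5e3))
}

ld_site_filter <- function(gm, config) {
  n_called <- rowSums(!is.na(gm$gt))
  n <- n_samples(gm)
  alt <- rowSums(gm$gt, na.rm = TRUE)
  maf <- ifelse(n_called > 0,
                pmin(alt, 2 * n_called - alt) / (2 * n_called), 0)
  hwe <- vapply(seq_len(n_sites(gm)), function(i) {
    g <- gm$gt[i, ]
    hwe_exact_p(sum(g == 0L, na.rm = TRUE), sum(g == 1L, na.rm = TRUE),
                sum(g == 2L, na.rm = TRUE))
  }, numeric(1))
  maf >= config$min_maf &
    n_called / n >= config$min_genotyped_fraction &
    hwe >= config$hwe_p_cutoff
}

#' LD-decay curve: mean r-squared per distance bin
#'
#' Sites are filtered by MAF, genotyped fraction and exact-HWE p-value;
#' all same-chromosome pairs within `max_distance` are formed (randomly
#' subsampled per bin beyond `max_pairs_per_bin`, using the current RNG
#' state), r2 is estimated per pair via [em_haplotype_freqs()], and means
#' are taken per distance bin.
#'
#' @param gm a [genotype_matrix()].
#' @param config an [ld_config()].
#' @param breaks distance-bin breaks (default [ld_distance_breaks()]).
#' @return Data frame of class `ld_curve`: `bin_low`, `bin_high`, `mid`,
#'   `mean_r2`, `n_pairs` (empty bins have `NA` mean and 0 pairs).
#' @export
ld_decay_curve <- function(gm, config = ld_config(),
                           breaks = ld_distance_breaks(config$max_distance)) {
  keep <- which(ld_site_filter(gm, config))
  pairs <- NULL
  if (length(keep) >= 2) {
    by_chr <- split(keep, gm$chrom[keep])
    pairs <- do.call(rbind, lapply(by_chr, function(idx) {
      if (length(idx) < 2) return(NULL)
      cmb <- utils::combn(idx, 2)
      d <- gm$pos[cmb[2, ]] - gm$pos[cmb[1, ]]
      ok <- d > 0 & d <= config$max_distance
      cbind(i = cmb[1, ok], j = cmb[2, ok], d = d[ok])
    }))
  }
  if (is.null(pairs) || nrow(pairs) == 0)
    stop("no site pairs pass the LD filters", call. = FALSE)
  bin <- cut(pairs[, "d"], breaks, right = TRUE, labels = FALSE)
  pairs <- pairs[!is.na(bin), , drop = FALSE]
  bin <- bin[!is.na(bin)]
  sel <- unlist(lapply(split(seq_len(nrow(pairs)), bin), function(ii) {
    if (length(ii) > config$max_pairs_per_bin)
      sample(ii, config$max_pairs_per_bin) else ii
  }), use.names = FALSE)
  pairs <- pairs[sel, , drop = FALSE]
  bin <- bin[sel]
  r2 <- vapply(seq_len(nrow(pairs)), function(k) {
    em <- em_haplotype_freqs(gm$gt[pairs[k, "i"], ], gm$gt[pairs[k, "j"], ])
    r_squared(em)$r2
  }, numeric(1))
  ok <- !is.na(r2)
  mean_r2 <- tapply(r2[ok], factor(bin[ok], seq_len(length(breaks) - 1)),
                    mean)
  n_pairs <- tapply(rep(1, sum(ok)), factor(bin[ok], seq_len(length(breaks) - 1)),
                    sum)
  out <- data.frame(bin_low = utils::head(breaks, -1), bin_high = breaks[-1],
                    mid = (utils::head(breaks, -1) + breaks[-1]) / 2,
                    mean_r2 = as.numeric(mean_r2),
                    n_pairs = ifelse(is.na(n_pairs), 0L, as.integer(n_pairs)))
  class(out) <- c("ld_curve", "data.frame")
  out
}

#' Distance at which mean r-squared falls to half its maximum
#'
#' Walks the non-empty bins (by midpoint) from the maximum outward and
#' returns the first distance at which the mean r2 drops to half the curve
#' maximum, linearly interpolating between adjacent bin midpoints.  If the
#' curve never reaches half-max, the result is censored at the largest
#' distance (`censored = TRUE`, reported as `> max distance`).
#'
#' @param curve an `ld_curve` (or data frame with `mid` and `mean_r2`).
#' @return List of class `half_max`: `distance` (bp), `censored`,
#'   `half_max` (the r2 level), `max_r2`.
#' @export
half_max_distance <- function(curve) {
  pts <- curve[!is.na(curve$mean_r2), c("mid", "mean_r2")]
  if (nrow(pts) == 0) stop("empty LD curve", call. = FALSE)
  m <- max(pts$mean_r2)
  if (m <= 0) stop("curve maximum must be > 0", call. = FALSE)
  half <- m / 2
  imax <- which.max(pts$mean_r2)
  dist <- NA_real_
  censored <- TRUE
  if (imax < nrow(pts) || pts$mean_r2[imax] <= half) {
    for (k in seq(imax, nrow(pts))) {
      if (pts$mean_r2[k] <= half) {
        if (k == imax || pts$mean_r2[k] == half) {
          dist <- pts$mid[k]
        } else {
          x0 <- pts$mid[k - 1]; y0 <- pts$mean_r2[k - 1]
          x1 <- pts$mid[k]; y1 <- pts$mean_r2[k]
          dist <- x0 + (y0 - half) / (y0 - y1) * (x1 - x0)
        }
        censored <- FALSE
        break
      }
    }
  }
  if (censored) dist <- max(pts$mid)
  structure(list(distance = dist, censored = censored, half_max = half,
                 max_r2 = m),
            class = "half_max")
}

#' @export
print.half_max <- function(x, ...) {
  if (x$censored)
    cat(sprintf("LD half-max not reached within %g bp (max r2 = %.3f)\n",
                x$distance, x$max_r2))
  else
    cat(sprintf("LD half-max distance: %.0f bp (r2 falls to %.3f)\n",
                x$distance, x$half_max))
  invisible(x)
}
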