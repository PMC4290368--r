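#' Per-individual heterozygosity rate
#'
#' Number of heterozygous genotypes carried by one individual divided by the
#' callable genome length, giving the per-bp heterozygosity printed in
#' genome-diversity tables (e.g. 0.43e-3 for a severely bottlenecked genome).
#' Missing genotypes are never counted.
#'
#' @param gm a [genotype_matrix()].
#' @param sample sample id.
#' @param callable_length callable genome length in bp (> 0).
#' @return Heterozygosity per bp.
#' @export
individual_heterozygosity <- function(gm, sample, callable_length) {
  stopifnot(callable_length > 0)
  if (!sample %in% gm$sample_ids)
    stop("unknown sample id: ", sample, call. = FALSE)
  sum(gm$gt[, sample] == 1L, na.rm = TRUE) / callable_length
}

#' Watterson's theta
#'
#' The population mutation parameter per bp, `theta_S = K / (a * L)`, with
#' `K` segregating sites found in `n` sampled chromosomes over `L` surveyed
#' bp and `a` the harmonic number `1 + 1/2 + ... + 1/(n-1)`.
#'
#' @param K number of segregating sites (>= 0).
#' @param n number of chromosomes sampled (>= 2).
#' @param L surveyed length in bp (> 0).
#' @return A list of class `theta_estimate` with fields `K`, `n`, `L`, `a`,
#'   `theta_s`.
#' @examples
#' watterson_theta(K = 11, n = 4, L = 1000)$theta_s  # 11 / (11/6 * 1000)
#' @export
watterson_theta <- function(K, n, L) {
  if (n < 2) stop("Watterson's estimator requires n >= 2", call. = FALSE)
  stopifnot(L > 0, K >= 0)
  a <- sum(1 / seq_len(n - 1))
  structure(list(K = K, n = n, L = L, a = a, theta_s = K / (a * L)),
            class = "theta_estimate")
}

#' @export
print.theta_estimate <- function(x, ...) {
  cat(sprintf("Watterson theta_S = %.4g per bp (K = %g, n = %g, L = %g, a = %.4f)\n",
              x$theta_s, x$K, x$n, x$L, x$a))
  invisible(x)
}

#' Windowed pooled heterozygosity (Hp)
#'
#' For each window, per-SNP major/minor allele read counts are summed over
#' the SNPs it contains and the pooled heterozygosity is computed once from
#' the sums: `Hp = 2 * S_maj * S_min / (S_maj + S_min)^2`, where
#' `S_maj = sum(n_maj)` and `S_min = sum(n_min)`.  Major/minor orientation
#' is fixed per SNP before summation.  Windows that are partial tiles or
#' contain fewer than `min_snps` SNPs are flagged and excluded from the
#' genome-wide standardization performed by [zhp_transform()].
#'
#' @param counts data frame with columns `chrom`, `pos` (1-based), and two
#'   allele read counts `n_maj`, `n_min` per SNP (orientation is enforced
#'   internally, so unordered count pairs are accepted).  See
#'   [counts_from_genotypes()] for the genotype-based fallback.
#' @param windows a window table from [make_windows()].
#' @param min_snps minimum SNPs per window for inclusion (default 10).
#' @return The window table with columns `n_snps`, `sum_n_maj`, `sum_n_min`,
#'   `hp`, `flag` (class `hp_windows`).
#' @export
window_hp <- function(counts, windows, min_snps = 10) {
  if (any(counts$n_maj < 0 | counts$n_min < 0))
    stop("negative read counts", call. = FALSE)
  maj <- pmax(counts$n_maj, counts$n_min)
  mnr <- pmin(counts$n_maj, counts$n_min)
  idx <- assign_windows(counts$chrom, counts$pos, windows)
  out <- windows
  out$n_snps <- vapply(idx, length, integer(1))
  out$sum_n_maj <- vapply(idx, function(i) sum(maj[i]), numeric(1))
  out$sum_n_min <- vapply(idx, function(i) sum(mnr[i]), numeric(1))
  tot <- out$sum_n_maj + out$sum_n_min
  out$hp <- ifelse(tot > 0, 2 * out$sum_n_maj * out$sum_n_min / tot^2, NA_real_)
  out$flag <- ifelse(out$partial, "partial",
                     ifelse(out$n_snps < min_snps, "low_snp", "."))
  class(out) <- c("hp_windows", class(windows))
  out
}

#' Z-standardize window Hp values
#'
#' `ZHp = (Hp - mean(Hp)) / sd(Hp)` over unflagged windows; `sd` is the
#' sample (n-1) standard deviation.  Flagged windows get `NA`.
#'
#' @param hpw an `hp_windows` table from [window_hp()], or a bare numeric
#'   vector of Hp values.
#' @return Same shape as the input with `zhp` attached (table) or the
#'   standardized vector.  Attributes `mu_hp` and `sigma_hp` record the
#'   genome-wide moments.
#' @export
zhp_transform <- function(hpw) {
  if (is.numeric(hpw)) {
    vals <- hpw
    keep <- !is.na(vals)
  } else {
    vals <- hpw$hp
    keep <- hpw$flag == "." & !is.na(vals)
  }
  if (sum(keep) < 2)
    stop("need >= 2 unflagged windows to standardize", call. = FALSE)
  mu <- mean(vals[keep])
  sigma <- stats::sd(vals[keep])
  if (sigma == 0)
    stop("sd(Hp) = 0: degenerate genome, ZHp undefined", call. = FALSE)
  z <- ifelse(keep, (vals - mu) / sigma, NA_real_)
  if (is.numeric(hpw)) {
    attr(z, "mu_hp") <- mu
    attr(z, "sigma_hp") <- sigma
    return(z)
  }
  hpw$zhp <- z
  attr(hpw, "mu_hp") <- mu
  attr(hpw, "sigma_hp") <- sigma
  hpw
}

#' Standard-normal quantile
#'
#' Inverse standard-normal CDF; `normal_quantile(0.01)` is the lower-tail
#' ZHp sweep threshold of -2.326.
#'
#' @param q tail probability in (0, 1).
#' @return The quantile `z` with `pnorm(z) = q`.
#' @export
normal_quantile <- function(q) {
  if (any(q <= 0 | q >= 1)) stop("q must be in (0, 1)", call. = FALSE)
  stats::qnorm(q)
}

#' Call putative sweep (allele-fixation) windows
#'
#' Flags windows whose ZHp is at or below the threshold (default the 1%
#' normal quantile, -2.326) and summarizes the count and percentage of
#' flagged windows among all standardized windows.
#'
#' @param hpw an `hp_windows` table with `zhp` (see [zhp_transform()]).
#' @param threshold ZHp cutoff (default `normal_quantile(0.01)`).
#' @return The table with a logical `sweep` column and `flag` set to
#'   `"sweep"` for calls; attribute `summary` holds `n_flagged`, `n_total`
#'   and `pct` (percentage, 1 decimal place).
#' @export
call_sweep_windows <- function(hpw, threshold = normal_quantile(0.01)) {
  eligible <- !is.na(hpw$zhp)
  hpw$sweep <- eligible & hpw$zhp <= threshold
  hpw$flag[hpw$sweep] <- "sweep"
  n_tot <- sum(eligible)
  n_fl <- sum(hpw$sweep)
  attr(hpw, "summary") <- list(
    n_flagged = n_fl, n_total = n_tot,
    pct = round(100 * n_fl / n_tot, 1), threshold = threshold)
  hpw
}

#' Genes overlapping flagged windows
#'
#' A gene is assigned to a window iff its interval overlaps the window by at
#' least 1 bp (both on 0-based half-open coordinates).  Genes within a
#' window are listed in position order.
#'
#' @param windows a window table (typically the `sweep` subset).
#' @param genes data frame with columns `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open).
#' @return A list, one character vector of gene ids per window row.
#' @export
annotate_windows_with_genes <- function(windows, genes) {
  lapply(seq_len(nrow(windows)), function(i) {
    hit <- genes$chrom == windows$chrom[i] &
      genes$start < windows$end[i] & genes$end > windows$start[i]
    g <- genes[hit, , drop = FALSE]
    g$gene_id[order(g$start)]
  })
}

#' Heterozygosity-decay series (Ht/H0)
#'
#' Normalizes per-individual heterozygosity by the mean heterozygosity of
#' the founder cohort, defined as all individuals carrying the earliest time
#' label.  Under pure drift in a Wright-Fisher population of size N the
#' expectation declines as `(1 - 1/(2N))^t`.
#'
#' @param het per-individual heterozygosity values.
#' @param time per-individual cohort labels (year or generation).
#' @return A data frame of class `decay_series` with `time`, `het`, `ratio`;
#'   attribute `h0` is the founder-cohort mean.
#' @export
ht_h0_series <- function(het, time) {
  stopifnot(length(het) == length(time), length(het) > 0)
  founder <- time == min(time)
  h0 <- mean(het[founder])
  if (!is.finite(h0) || h0 <= 0)
    stop("founder-cohort mean heterozygosity must be > 0", call. = FALSE)
  out <- data.frame(time = time, het = het, ratio = het / h0)
  attr(out, "h0") <- h0
  class(out) <- c("decay_series", "data.frame")
  out
}

#' Linear regression of Ht/H0 on time
#'
#' Ordinary least squares of the heterozygosity ratio on time, with the
#' Pearson correlation and the two-sided p-value from the t distribution on
#' n - 2 degrees of freedom.
#'
#' @param series a `decay_series` from [ht_h0_series()], or any data frame
#'   with `time` and `ratio` columns.
#' @return A list of class `decay_fit`: `slope`, `intercept`, `pearson_r`,
#'   `p_value`, `slope_se`, `ci95` (95% confidence interval on the slope),
#'   `n`.
#' @export
decay_regression <- function(series) {
  t <- series$time; y <- series$ratio
  if (length(t) < 3) stop("need >= 3 points", call. = FALSE)
  if (length(unique(t)) < 2) stop("all times equal", call. = FALSE)
  fit <- stats::lm(y ~ t)
  sm <- summary(fit)
  slope <- unname(stats::coef(fit)[2])
  se <- sm$coefficients[2, 2]
  p <- sm$coefficients[2, 4]
  r <- stats::cor(t, y)
  tcrit <- stats::qt(0.975, df = length(t) - 2)
  structure(list(slope = slope, intercept = unname(stats::coef(fit)[1]),
                 pearson_r = r, p_value = p, slope_se = se,
                 ci95 = c(slope - tcrit * se, slope + tcrit * se),
                 n = length(t)),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("Ht/H0 decay: slope = %.4g per unit time (95%% CI %.4g..%.4g), r = %.3f, p = %.3g, n = %d\n",
              x$slope, x$ci95[1], x$ci95[2], x$pearson_r, x$p_value, x$n))
  invisible(x)
}

#' Neutral mutation rate from divergence
#'
#' `mu = divergence * generation_time / (2 * divergence_time)`, mutations
#' per site per generation — e.g. genome-wide nucleotide divergence 0.1031,
#' a 3-year generation time and a 38.98 Myr split give 3.968e-9.
#'
#' @param divergence genome-wide nucleotide divergence (proportion).
#' @param generation_time_years mean generation time in years.
#' @param divergence_time_years split time in years.
#' @return Mutation rate per site per generation.
#' @export
neutral_mutation_rate <- function(divergence, generation_time_years,
                                  divergence_time_years) {
  stopifnot(divergence >= 0, generation_time_years > 0,
            divergence_time_years > 0)
  divergence * generation_time_years / (2 * divergence_time_years)
}
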