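#' Weir-Cockerham fixation index among subpopulations
#'
#' Per-locus variance components following Weir & Cockerham's
#' moment estimator for random-union-of-gametes populations: `a` (among
#' subpopulations), `b` (among individuals within subpopulations) and `c`
#' (within individuals), with the genome-wide estimate formed as the ratio
#' of summed components `sum(a) / sum(a + b + c)` — the ratio-of-averages
#' combination, which is invariant to duplicating every individual.  Loci
#' monomorphic across all subpopulations are skipped.
#'
#' @param gm a [genotype_matrix()].
#' @param pops character/factor of subpopulation labels, one per sample.
#' @return List of class `fst_result`: `per_locus` (data frame with `site`,
#'   `a`, `b`, `c`, `theta`), `theta_global`, `n_loci_used`.
#' @examples
#' gm <- genotype_matrix("chr1", 1L, "A", "G",
#'                       matrix(c(0L, 0L, 2L, 2L), 1), paste0("s", 1:4))
#' weir_cockerham_fst(gm, c("p1", "p1", "p2", "p2"))$theta_global  # 1
#' @export
weir_cockerham_fst <- function(gm, pops) {
  pops <- as.character(pops)
  stopifnot(length(pops) == n_samples(gm))
  lev <- unique(pops)
  r <- length(lev)
  if (r < 2) stop("need >= 2 subpopulations", call. = FALSE)
  rows <- vector("list", n_sites(gm))
  for (s in seq_len(n_sites(gm))) {
    g <- gm$gt[s, ]
    ni <- vapply(lev, function(p) sum(!is.na(g[pops == p])), numeric(1))
    if (any(ni == 0)) next
    pi <- vapply(lev, function(p) {
      gi <- g[pops == p]
      sum(gi, na.rm = TRUE) / (2 * sum(!is.na(gi)))
    }, numeric(1))
    hi <- vapply(lev, function(p) {
      gi <- g[pops == p]
      mean(gi == 1L, na.rm = TRUE)
    }, numeric(1))
    nbar <- mean(ni)
    pbar <- sum(ni * pi) / (r * nbar)
    if (pbar <= 0 || pbar >= 1) next       # monomorphic overall
    if (nbar <= 1) next
    nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
    s2 <- sum(ni * (pi - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(ni * hi) / (r * nbar)
    a <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    theta <- if ((a + b + cc) != 0) a / (a + b + cc) else NA_real_
    rows[[s]] <- data.frame(site = s, a = a, b = b, c = cc, theta = theta)
  }
  per_locus <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(per_locus) || nrow(per_locus) == 0)
    stop("no polymorphic locus with all subpopulations genotyped",
         call. = FALSE)
  theta_global <- sum(per_locus$a) /
    sum(per_locus$a + per_locus$b + per_locus$c)
  structure(list(per_locus = per_locus, theta_global = theta_global,
                 n_loci_used = nrow(per_locus), pops = lev),
            class = "fst_result")
}

#' @export
print.fst_result <- function(x, ...) {
  cat(sprintf("Weir-Cockerham FST = %.4f over %d loci, %d subpopulations\n",
              x$theta_global, x$n_loci_used, length(x$pops)))
  invisible(x)
}
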