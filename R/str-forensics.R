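#' Scan a sequence for perfect (non-degenerate) STRs
#'
#' Finds maximal exact tandem runs of 2-6 bp units: stretches where every
#' base equals the base one unit earlier, containing no insertions,
#' deletions or mismatches.  Runs containing `N` are broken.  A run is
#' reported at the smallest unit size that explains it (a region that is
#' also periodic at some smaller period is skipped at the larger unit, so
#' e.g. `ATATATAT` is a 2-bp locus, never a 4-bp one), with its left-most
#' maximal extent, at least two complete repeats, and total length at least
#' `min_total_length`.
#'
#' @param sequence DNA sequence as a single string over `A C G T N`.
#' @param unit_sizes repeat-unit sizes to scan (default 2:6).
#' @param min_total_length minimum run length in bp (default 8).
#' @return Data frame: `start` (0-based), `end` (exclusive), `unit_size`,
#'   `n_repeats` (complete units), `unit` (first unit of the run).
#' @examples
#' scan_perfect_strs("TTACACACACGG")
#' @export
scan_perfect_strs <- function(sequence, unit_sizes = 2:6,
                              min_total_length = 8) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  n <- length(chars)
  out <- list()
  for (u in unit_sizes) {
    if (n < 2 * u) next
    lhs <- chars[(u + 1):n]
    rhs <- chars[1:(n - u)]
    eq <- lhs == rhs & lhs != "N" & rhs != "N"
    r <- rle(eq)
    ends_rel <- cumsum(r$lengths)
    starts_rel <- ends_rel - r$lengths + 1
    for (k in which(r$values)) {
      match_len <- r$lengths[k]
      if (match_len < u) next                    # fewer than 2 full units
      start0 <- starts_rel[k] - 1                # 0-based region start
      len <- match_len + u
      if (len < min_total_length) next
      region <- chars[(start0 + 1):(start0 + len)]
      # primitive at u: region must not be periodic at any smaller period
      smaller <- FALSE
      for (v in seq_len(u - 1)) {
        if (all(region[(v + 1):len] == region[1:(len - v)])) {
          smaller <- TRUE; break
        }
      }
      if (smaller) next
      out[[length(out) + 1]] <- data.frame(
        start = start0, end = start0 + len, unit_size = u,
        n_repeats = len %/% u,
        unit = paste(region[1:u], collapse = ""),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(start = integer(), end = integer(),
                      unit_size = integer(), n_repeats = integer(),
                      unit = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$unit_size), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Per-locus STR summary
#'
#' Allele frequencies from the 2n observed alleles, number of distinct
#' alleles, major allele (ties break toward the smaller repeat count),
#' major-minor size differences in bp, and expected heterozygosity
#' `He = 1 - sum(p_i^2)`.
#'
#' @param tbl an [str_genotype_table()].
#' @param locus locus id.
#' @return List of class `str_locus_summary`: `locus_id`, `unit_size`,
#'   `allele_freqs` (named, by repeat count), `n_alleles`, `major`,
#'   `minors`, `size_differences_bp`, `expected_heterozygosity`, `n_obs`
#'   (observed allele count).
#' @export
str_locus_summary <- function(tbl, locus) {
  stopifnot(locus %in% tbl$locus_ids)
  alleles <- c(tbl$a1[, locus], tbl$a2[, locus])
  alleles <- alleles[!is.na(alleles)]
  if (length(alleles) == 0)
    stop("all genotypes missing at locus ", locus, call. = FALSE)
  cnt <- table(alleles)
  vals <- as.numeric(names(cnt))
  freqs <- as.numeric(cnt) / length(alleles)
  names(freqs) <- names(cnt)
  major <- vals[order(-freqs, vals)][1]
  minors <- sort(vals[vals != major])
  unit <- tbl$unit_size[[locus]]
  structure(list(locus_id = locus, unit_size = unit,
                 allele_freqs = freqs, n_alleles = length(vals),
                 major = major, minors = minors,
                 size_differences_bp = abs(major - minors) * unit,
                 expected_heterozygosity = 1 - sum(freqs^2),
                 n_obs = length(alleles)),
            class = "str_locus_summary")
}

#' Fraction of polymorphic STR loci by unit size
#'
#' Per repeat-unit-size class, the fraction of loci carrying at least
#' `min_alleles` distinct alleles.
#'
#' @param summaries list of [str_locus_summary()] results.
#' @param min_alleles allele-count threshold (default 4).
#' @return Data frame: `unit_size`, `n_loci`, `n_polymorphic`, `fraction`.
#' @export
polymorphic_fraction <- function(summaries, min_alleles = 4) {
  stopifnot(length(summaries) > 0)
  unit <- vapply(summaries, `[[`, numeric(1), "unit_size")
  poly <- vapply(summaries, `[[`, numeric(1), "n_alleles") >= min_alleles
  us <- sort(unique(unit))
  data.frame(unit_size = us,
             n_loci = vapply(us, function(u) sum(unit == u), numeric(1)),
             n_polymorphic = vapply(us, function(u) sum(poly[unit == u]),
                                    numeric(1)),
             fraction = vapply(us, function(u) mean(poly[unit == u]),
                               numeric(1)))
}

#' Match probability and discrimination power at one STR locus
#'
#' Forensic power of discrimination from *observed* genotype frequencies
#' (counting unordered genotypes, not HWE expectations):
#' `PM = sum(genotype frequency^2)`, `PD = 1 - PM`.
#'
#' @param tbl an [str_genotype_table()].
#' @param locus locus id.
#' @return List: `pm`, `pd`, `n` (genotyped individuals).
#' @export
match_probability <- function(tbl, locus) {
  stopifnot(locus %in% tbl$locus_ids)
  a1 <- tbl$a1[, locus]; a2 <- tbl$a2[, locus]
  ok <- !is.na(a1)
  if (!any(ok)) stop("no genotypes at locus ", locus, call. = FALSE)
  key <- paste(pmin(a1[ok], a2[ok]), pmax(a1[ok], a2[ok]), sep = "/")
  gf <- as.numeric(table(key)) / sum(ok)
  pm <- sum(gf^2)
  list(pm = pm, pd = 1 - pm, n = sum(ok))
}

#' Combined forensic panel statistics
#'
#' Combined discrimination power `1 - prod(PM_i)` and combined exclusion
#' probability `1 - prod(1 - PE_i)` over a panel of STR loci, alongside the
#' per-locus values and their mean.
#'
#' @param tbl an [str_genotype_table()].
#' @param loci locus ids (default all).
#' @return List of class `forensic_panel`: `per_locus` (data frame with
#'   `locus_id`, `pm`, `pd`, `pe`, `he`), `combined_pd`, `combined_pe`,
#'   `mean_pd`, `mean_pe`.
#' @export
forensic_panel <- function(tbl, loci = tbl$locus_ids) {
  per <- do.call(rbind, lapply(loci, function(lc) {
    mp <- match_probability(tbl, lc)
    sm <- str_locus_summary(tbl, lc)
    data.frame(locus_id = lc, pm = mp$pm, pd = mp$pd,
               pe = exclusion_probability(sm$allele_freqs),
               he = sm$expected_heterozygosity,
               stringsAsFactors = FALSE)
  }))
  structure(list(per_locus = per,
                 combined_pd = 1 - prod(per$pm),
                 combined_pe = 1 - prod(1 - per$pe),
                 mean_pd = mean(per$pd), mean_pe = mean(per$pe)),
            class = "forensic_panel")
}

#' @export
print.forensic_panel <- function(x, ...) {
  cat(sprintf("forensic panel: %d loci, combined PD = %.4f (per-locus mean %.3f), combined PE = %.4f\n",
              nrow(x$per_locus), x$combined_pd, x$mean_pd, x$combined_pe))
  invisible(x)
}

#' Paternity exclusion probability at one locus
#'
#' Probability that a random unrelated man is excluded by Mendelian
#' inconsistency in a mother-child case, computed by exact enumeration over
#' all (mother genotype, maternal allele, true paternal allele, random man)
#' combinations under Hardy-Weinberg proportions — no closed form is relied
#' upon.  The man is excluded iff he carries none of the alleles that could
#' be the child's paternal allele given the mother.
#'
#' @param freqs named numeric vector of allele frequencies (sum to 1).
#' @return Per-locus exclusion probability (0 for a monomorphic locus).
#' @export
exclusion_probability <- function(freqs) {
  p <- as.numeric(freqs)
  stopifnot(all(p >= 0), abs(sum(p) - 1) < 1e-8)
  k <- length(p)
  if (k < 2) return(0)
  pe <- 0
  for (i in seq_len(k)) for (j in seq_len(k)) {    # mother ordered genotype
    pm_gt <- p[i] * p[j]
    if (pm_gt == 0) next
    for (midx in c(i, j)) {                        # transmitted maternal allele
      for (f in seq_len(k)) {                      # true paternal allele
        w <- pm_gt * 0.5 * p[f]
        if (w == 0) next
        # possible paternal alleles given mother {i,j} and child {midx, f}
        cand <- unique(c(if (f %in% c(i, j)) midx, if (midx %in% c(i, j)) f))
        q <- sum(p[cand])
        pe <- pe + w * (1 - q)^2
      }
    }
  }
  pe
}

#' Paternity index for a mother-child-alleged-father trio
#'
#' Per-locus likelihood ratio
#' `PI = P(child | mother, alleged father) / P(child | mother, random man)`
#' by Mendelian enumeration of transmission probabilities, with the random
#' man's contribution taken from the population allele frequencies.
#'
#' @param mother,child,af numeric length-2 genotypes (allele pairs).
#' @param freqs named numeric allele-frequency vector for the locus.
#' @param locus locus label used in error messages.
#' @return The paternity index (possibly 0 when the alleged father lacks
#'   every possible obligate allele, or `Inf` when the random-man
#'   denominator is 0).
#' @export
paternity_index <- function(mother, child, af, freqs, locus = "?") {
  trans <- function(gt, a) sum(gt == a) / 2
  pf <- function(a) {
    i <- match(as.character(a), names(freqs))
    if (is.na(i)) 0 else as.numeric(freqs[i])
  }
  x <- child[1]; y <- child[2]
  if (x == y) {
    num <- trans(mother, x) * trans(af, x)
    den <- trans(mother, x) * pf(x)
  } else {
    num <- trans(mother, x) * trans(af, y) + trans(mother, y) * trans(af, x)
    den <- trans(mother, x) * pf(y) + trans(mother, y) * pf(x)
  }
  if (trans(mother, x) == 0 && trans(mother, y) == 0)
    stop("mother-child incompatibility at locus ", locus, call. = FALSE)
  if (den == 0) return(Inf)
  num / den
}

#' Combined paternity index and probability of paternity
#'
#' The combined PI is the product of per-locus indices; the probability of
#' paternity converts it with a prior (forensic convention 0.5):
#' `W = PI * prior / (PI * prior + 1 - prior)`.
#'
#' @param tbl an [str_genotype_table()].
#' @param mother_id,child_id,af_id sample ids of the trio.
#' @param loci locus ids (default all); loci with any missing trio genotype
#'   are skipped.
#' @return List of class `paternity_result`: `per_locus` (data frame),
#'   `combined_pi`, `w`, `prior`.
#' @export
#' @rdname paternity_index
trio_paternity <- function(tbl, mother_id, child_id, af_id,
                           loci = tbl$locus_ids, prior = 0.5) {
  rows <- list()
  for (lc in loci) {
    m <- c(tbl$a1[mother_id, lc], tbl$a2[mother_id, lc])
    ch <- c(tbl$a1[child_id, lc], tbl$a2[child_id, lc])
    f <- c(tbl$a1[af_id, lc], tbl$a2[af_id, lc])
    if (anyNA(c(m, ch, f))) next
    freqs <- str_locus_summary(tbl, lc)$allele_freqs
    rows[[length(rows) + 1]] <- data.frame(
      locus_id = lc, pi = paternity_index(m, ch, f, freqs, lc),
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no complete trio genotypes", call. = FALSE)
  per <- do.call(rbind, rows)
  cpi <- prod(per$pi)
  structure(list(per_locus = per, combined_pi = cpi,
                 w = probability_of_paternity(cpi, prior), prior = prior),
            class = "paternity_result")
}

#' @rdname paternity_index
#' @param combined_pi product of per-locus paternity indices.
#' @param prior prior probability of paternity (default 0.5).
#' @export
probability_of_paternity <- function(combined_pi, prior = 0.5) {
  if (is.infinite(combined_pi)) return(1)
  combined_pi * prior / (combined_pi * prior + (1 - prior))
}

#' W-linked marker sex call
#'
#' Birds are ZZ (male) / ZW (female).  A W-specific insertion allele
#' (`z_length + insertion` bp) is carried only by females: its presence
#' calls ZW, a valid Z-only profile calls ZZ, anything else (including a
#' missing genotype) is inconclusive.
#'
#' @param alleles numeric length-2 fragment lengths at the W-linked marker
#'   (or `NA`s when missing).
#' @param z_length fragment length of the Z-chromosome allele (bp).
#' @param insertion W-specific insertion size in bp (default 31).
#' @return `"ZW"`, `"ZZ"` or `"inconclusive"`.
#' @export
sex_call <- function(alleles, z_length, insertion = 31) {
  if (anyNA(alleles)) return("inconclusive")
  if (any(alleles == z_length + insertion)) return("ZW")
  if (all(alleles == z_length)) return("ZZ")
  "inconclusive"
}
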