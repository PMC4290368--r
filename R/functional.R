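#' CDS gene model
#'
#' A minimal coding-sequence description sufficient to reconstruct codons:
#' exon intervals in genomic order (0-based half-open), the coding strand,
#' and the phase of the first coding base (0 for a complete first codon).
#' On the `-` strand the 5'->3' coding order is the reverse of the genomic
#' order and bases are complemented.
#'
#' @param gene_id gene identifier.
#' @param chrom chromosome label.
#' @param strand `"+"` or `"-"`.
#' @param exons two-column matrix or data frame of 0-based half-open exon
#'   intervals in ascending genomic order, non-overlapping.
#' @param phase 0, 1 or 2: number of bases of the first (5'-most) codon
#'   missing from this model.
#' @return An object of class `cds_model`.
#' @export
cds_model <- function(gene_id, chrom, strand, exons, phase = 0L) {
  exons <- as.matrix(exons)
  colnames(exons) <- c("start", "end")
  stopifnot(strand %in% c("+", "-"), phase %in% 0:2,
            all(exons[, 2] > exons[, 1]))
  if (nrow(exons) > 1) {
    o <- order(exons[, 1])
    exons <- exons[o, , drop = FALSE]
    if (any(exons[-1, 1] < exons[-nrow(exons), 2]))
      stop("overlapping exons", call. = FALSE)
  }
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 exons = exons, phase = as.integer(phase)),
            class = "cds_model")
}

cds_length <- function(cds) sum(cds$exons[, 2] - cds$exons[, 1])

# genomic 0-based positions of the CDS in 5'->3' coding order
cds_genomic_positions <- function(cds) {
  p <- unlist(lapply(seq_len(nrow(cds$exons)),
                     function(i) seq(cds$exons[i, 1], cds$exons[i, 2] - 1)))
  if (cds$strand == "-") rev(p) else p
}

comp_base <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

translate_codon <- function(codon) {
  seqinr::translate(strsplit(codon, "")[[1]])
}

#' Classify a coding SNP by codon substitution
#'
#' Reconstructs the codon containing the site on the coding strand
#' (reverse-complementing for `-` strand genes, including codons split
#' across exon junctions) and compares the translation of the reference and
#' alternate codons under the standard genetic code.
#'
#' Effects: `synonymous` (same amino acid), `missense`, `stop_gain`
#' (amino acid -> stop), `stop_loss` (stop -> amino acid), `start_loss`
#' (change away from the initiator ATG).  `stop_gain` and `start_loss` are
#' loss-of-function for SNPs.
#'
#' @param cds a [cds_model()].
#' @param chrom_seq chromosome sequence as a single character string
#'   (plus strand).
#' @param pos 1-based genomic position of the SNP.
#' @param ref,alt reference and alternate bases on the plus strand.
#' @return A list of class `coding_effect`: `gene_id`, `codon_index`
#'   (1-based), `codon_pos` (1-3 within codon, coding strand), `ref_codon`,
#'   `alt_codon`, `ref_aa`, `alt_aa`, `effect`, `lof`.
#' @examples
#' cds <- cds_model("g", "chr1", "+", cbind(0, 9))
#' classify_coding_snp(cds, "ATGTGGTAA", 6, "G", "A")$effect  # TGG->TGA stop_gain
#' @export
classify_coding_snp <- function(cds, chrom_seq, pos, ref, alt) {
  p0 <- pos - 1
  gpos <- cds_genomic_positions(cds)
  cpos <- match(p0, gpos)  # 1-based index along coding sequence
  if (is.na(cpos))
    stop("site ", pos, " outside the CDS of ", cds$gene_id, call. = FALSE)
  seq_base <- substr(chrom_seq, pos, pos)
  if (seq_base != ref)
    stop("reference mismatch at ", cds$chrom, ":", pos, " (sequence ",
         seq_base, ", ref ", ref, ")", call. = FALSE)
  cpos_adj <- cpos - cds$phase
  if (cpos_adj < 1)
    stop("site ", pos, " falls in the incomplete leading codon of ",
         cds$gene_id, call. = FALSE)
  codon_index <- (cpos_adj - 1) %/% 3 + 1
  codon_pos <- (cpos_adj - 1) %% 3 + 1
  codon_c <- (codon_index - 1) * 3 + cds$phase + 1:3
  if (any(codon_c > length(gpos)))
    stop("site ", pos, " falls in an incomplete terminal codon of ",
         cds$gene_id, call. = FALSE)
  fetch <- function(alt_at_site) {
    bases <- vapply(codon_c, function(ci) {
      g <- gpos[ci]
      b <- if (alt_at_site && g == p0) alt else substr(chrom_seq, g + 1, g + 1)
      if (cds$strand == "-") unname(comp_base[b]) else b
    }, character(1))
    paste(bases, collapse = "")
  }
  ref_codon <- fetch(FALSE)
  alt_codon <- fetch(TRUE)
  ref_aa <- translate_codon(ref_codon)
  alt_aa <- translate_codon(alt_codon)
  effect <-
    if (codon_index == 1 && cds$phase == 0 && ref_codon == "ATG" &&
        alt_codon != "ATG") "start_loss"
    else if (ref_aa != "*" && alt_aa == "*") "stop_gain"
    else if (ref_aa == "*" && alt_aa != "*") "stop_loss"
    else if (ref_aa == alt_aa) "synonymous"
    else "missense"
  structure(list(gene_id = cds$gene_id, codon_index = codon_index,
                 codon_pos = codon_pos, ref_codon = ref_codon,
                 alt_codon = alt_codon, ref_aa = ref_aa, alt_aa = alt_aa,
                 effect = effect,
                 lof = effect %in% c("stop_gain", "start_loss")),
            class = "coding_effect")
}

#' Classify every coding SNP of a genotype matrix
#'
#' Convenience wrapper over [classify_coding_snp()]: sites outside every
#' CDS, or in incomplete leading/terminal codons, are skipped with a count
#' reported in attribute `n_skipped`.
#'
#' @param gm a [genotype_matrix()].
#' @param cds_list list of [cds_model()] objects.
#' @param genome named list/vector of chromosome sequences (plus strand).
#' @return Data frame with columns `site` (row index into `gm`), `gene_id`,
#'   `effect`, `lof`.
#' @export
annotate_effects <- function(gm, cds_list, genome) {
  rows <- list()
  n_skipped <- 0L
  for (i in seq_len(n_sites(gm))) {
    for (cds in cds_list) {
      if (cds$chrom != gm$chrom[i]) next
      p0 <- gm$pos[i] - 1
      inside <- any(p0 >= cds$exons[, 1] & p0 < cds$exons[, 2])
      if (!inside) next
      eff <- tryCatch(
        classify_coding_snp(cds, genome[[cds$chrom]], gm$pos[i],
                            gm$ref[i], gm$alt[i]),
        error = function(e) NULL)
      if (is.null(eff)) { n_skipped <- n_skipped + 1L; next }
      rows[[length(rows) + 1]] <- data.frame(
        site = i, gene_id = eff$gene_id, effect = eff$effect,
        lof = eff$lof, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(site = integer(), gene_id = character(),
                         effect = character(), lof = logical())
  attr(out, "n_skipped") <- n_skipped
  out
}

#' NS/S ratio of heterozygous coding SNPs
#'
#' Count ratio of non-synonymous (missense + stop_gain + stop_loss +
#' start_loss) to synonymous heterozygous sites in one genome — the
#' per-genome "non-synonymous/synonymous heterozygosity" statistic used to
#' compare endangered against least-concern species.  Returns `NA` when the
#' genome has no synonymous heterozygote (ratio undefined).
#'
#' @param effects character vector of effect labels for the heterozygous
#'   coding SNPs of one individual (as from [annotate_effects()] subset to
#'   `gt == 1`).
#' @return Non-synonymous/synonymous count ratio, or `NA_real_`.
#' @export
ns_s_ratio <- function(effects) {
  ns <- sum(effects %in% c("missense", "stop_gain", "stop_loss", "start_loss"))
  s <- sum(effects == "synonymous")
  if (s == 0) return(NA_real_)
  ns / s
}

#' Derived-allele-frequency spectrum by effect class
#'
#' The derived allele at each site is the non-ancestral allele; its
#' frequency is computed over non-missing genotypes.  Sites without
#' ancestral information, or where the ancestral allele matches neither ref
#' nor alt, are excluded with counts reported in attributes `n_no_anc` /
#' `n_anc_mismatch`.  Frequencies are binned into intervals of `bin_width`
#' partitioning (0, 1]; sites with derived frequency 0 carry no derived
#' allele and are dropped.  Per class, bin fractions sum to 1.
#'
#' @param gm a [genotype_matrix()] with ancestral alleles.
#' @param class optional per-site class labels (e.g. `"NS"`/`"S"`), recycled
#'   to `n_sites(gm)`; default a single class `"all"`.
#' @param bin_width bin width in (0, 1] (default 0.1).
#' @return A data frame: `class`, `bin_low`, `bin_high`, `fraction`, `count`.
#' @export
daf_spectrum <- function(gm, class = "all", bin_width = 0.1) {
  if (length(class) == 1) class <- rep(class, n_sites(gm))
  anc_raw <- gm$anc
  usable <- !is.na(anc_raw)
  n_no_anc <- sum(!usable)
  if (!any(usable))
    stop("no sites with ancestral information", call. = FALSE)
  # constructor guarantees anc in {ref, alt, NA}; mismatches would have
  # been rejected, but count defensively for externally built objects
  mism <- usable & anc_raw != gm$ref & anc_raw != gm$alt
  usable <- usable & !mism
  derived_is_alt <- gm$anc == gm$ref
  n_called <- rowSums(!is.na(gm$gt))
  alt_count <- rowSums(gm$gt, na.rm = TRUE)
  dcount <- ifelse(derived_is_alt, alt_count, 2 * n_called - alt_count)
  freq <- ifelse(n_called > 0, dcount / (2 * n_called), NA_real_)
  keep <- usable & !is.na(freq) & freq > 0
  breaks <- seq(0, 1, by = bin_width)
  out <- do.call(rbind, lapply(unique(class), function(cl) {
    f <- freq[keep & class == cl]
    cnt <- as.integer(table(cut(f, breaks, right = TRUE)))
    data.frame(class = cl, bin_low = utils::head(breaks, -1),
               bin_high = breaks[-1],
               fraction = if (length(f)) cnt / length(f) else NA_real_,
               count = cnt, stringsAsFactors = FALSE)
  }))
  attr(out, "n_no_anc") <- n_no_anc
  attr(out, "n_anc_mismatch") <- sum(mism)
  out
}

#' Fisher's exact test for a 2x2 table
#'
#' Exact hypergeometric enumeration over tables with the observed margins
#' (no approximation).  The table is
#' \preformatted{  a  b   (group 1)
#'   c  d   (group 2)}
#' `p_greater` tests enrichment of the first column in group 1,
#' `p_less` the opposite direction, and `p_two` sums the probabilities of
#' all tables no more probable than the observed one.
#'
#' @param a,b,c,d non-negative integer cell counts.
#' @return List with `p_less`, `p_greater`, `p_two`.
#' @examples
#' # e.g. a gene inactivated in 3 of 8 endangered vs 0 of 15 least-concern
#' fisher_exact_2x2(3, 5, 0, 15)$p_greater  # 56/1771
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0,
            a == round(a), b == round(b), c == round(c), d == round(d))
  m <- a + b        # group 1 size
  n <- c + d        # group 2 size
  k <- a + c        # first-column total
  lo <- max(0, k - n)
  hi <- min(k, m)
  x <- lo:hi
  probs <- stats::dhyper(x, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  list(p_less = sum(probs[x <= a]),
       p_greater = sum(probs[x >= a]),
       p_two = sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Per-gene loss-of-function enrichment between species groups
#'
#' For each gene, a 2x2 table (LoF vs intact x group A vs group B) is tested
#' one-sided in each direction by [fisher_exact_2x2()].  Genes significant
#' at `alpha` are returned per direction.  Unadjusted p-values are used by
#' default; `adjust = "BH"` applies Benjamini-Hochberg within each
#' direction instead.
#'
#' @param lof_matrix logical/0-1 matrix, genes x species: gene inactivated
#'   in that species.
#' @param groups factor/character of length `ncol(lof_matrix)` with exactly
#'   two levels (e.g. `"EV"`, `"LC"`).
#' @param alpha significance level (default 0.05).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return List with `table` (per-gene counts and p-values) and per-level
#'   significant gene-id vectors `enriched` (named by group level).
#' @export
lof_enrichment <- function(lof_matrix, groups, alpha = 0.05,
                           adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  groups <- as.character(groups)
  lev <- unique(groups)
  if (length(lev) != 2) stop("need exactly two groups", call. = FALSE)
  if (min(table(groups)) == 0) stop("empty group", call. = FALSE)
  g1 <- groups == lev[1]
  lof_matrix <- as.matrix(lof_matrix) > 0
  a <- rowSums(lof_matrix[, g1, drop = FALSE])
  c_ <- rowSums(lof_matrix[, !g1, drop = FALSE])
  b <- sum(g1) - a
  d <- sum(!g1) - c_
  p1 <- mapply(function(a, b, c, d) fisher_exact_2x2(a, b, c, d)$p_greater,
               a, b, c_, d)
  p2 <- mapply(function(a, b, c, d) fisher_exact_2x2(a, b, c, d)$p_less,
               a, b, c_, d)
  if (adjust == "BH") {
    p1a <- stats::p.adjust(p1, "BH")
    p2a <- stats::p.adjust(p2, "BH")
  } else {
    p1a <- p1; p2a <- p2
  }
  ids <- rownames(lof_matrix)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(lof_matrix)))
  tab <- data.frame(gene_id = ids, lof_g1 = a, n_g1 = sum(g1),
                    lof_g2 = c_, n_g2 = sum(!g1),
                    p_g1 = p1, p_g2 = p2, stringsAsFactors = FALSE)
  names(tab)[names(tab) == "p_g1"] <- paste0("p_", lev[1])
  names(tab)[names(tab) == "p_g2"] <- paste0("p_", lev[2])
  enr <- stats::setNames(list(ids[p1a < alpha], ids[p2a < alpha]), lev)
  list(table = tab, enriched = enr, alpha = alpha, adjust = adjust)
}
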