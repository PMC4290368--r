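# Standard genetic code, bases in T/C/A/G order (kept separate from the
# classifier's translation path so implant labels and classification form
# two independent routes).
GEN_CODE_AA <- strsplit(
  "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG",
  "")[[1]]
GEN_CODE_CODONS <- {
  b <- c("T", "C", "A", "G")
  paste0(rep(b, each = 16), rep(rep(b, each = 4), 4), rep(b, 16))
}
GEN_CODE <- stats::setNames(GEN_CODE_AA, GEN_CODE_CODONS)

revcomp <- function(s) {
  paste(rev(unname(comp_base[strsplit(s, "")[[1]]])), collapse = "")
}

random_orf <- function(n_codons) {
  sense <- names(GEN_CODE)[GEN_CODE != "*" & names(GEN_CODE) != "ATG"]
  paste0("ATG",
         paste(sample(sense, n_codons, replace = TRUE), collapse = ""),
         sample(c("TAA", "TAG", "TGA"), 1))
}

#' Generate a synthetic coding landscape with effect-labelled variants
#'
#' Builds a random chromosome carrying non-overlapping multi-exon genes on
#' both strands (valid ORFs: ATG start, no internal stop, terminal stop;
#' 1-5 exons with codons freely split across junctions), then implants SNPs
#' with known effect labels: `n_syn` synonymous variants and
#' `round(ns_ratio * n_syn)` non-synonymous ones (missense, with a fixed
#' share of stop-gains), at distinct genomic sites.  Implant labels are
#' derived from a self-contained codon table, independent of the
#' classifier's coordinate machinery, so recovering them exercises the full
#' exon/strand mapping.
#'
#' @param genome_length chromosome length in bp.
#' @param n_genes number of genes.
#' @param n_syn number of synonymous implants.
#' @param ns_ratio target NS/S count ratio (default 0.69, a typical
#'   bottlenecked-genome value).
#' @param stop_gain_share share of non-synonymous implants that are
#'   stop-gains (default 0.05).
#' @param seed RNG seed.
#' @return List of class `cds_landscape`: `genome` (named list of
#'   chromosome strings), `cds_list` (list of [cds_model()]), `variants`
#'   (data frame: `chrom`, `pos` 1-based, `ref`, `alt`, `gene_id`,
#'   `true_effect`).
#' @export
generate_cds_landscape <- function(genome_length = 5e4, n_genes = 8,
                                   n_syn = 100, ns_ratio = 0.69,
                                   stop_gain_share = 0.05, seed = 1L) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  chrom <- "chr1"
  seq_chars <- sample(bases, genome_length, replace = TRUE)
  cds_list <- list()
  cursor <- 1L  # next free 1-based position
  for (g in seq_len(n_genes)) {
    n_cod <- sample(30:80, 1)
    cds_len <- 3L * (n_cod + 2L)
    n_ex <- sample(1:5, 1)
    n_ex <- min(n_ex, cds_len %/% 3)
    cuts <- if (n_ex > 1) sort(sample(seq_len(cds_len - 1), n_ex - 1)) else integer()
    ex_lens <- diff(c(0L, cuts, cds_len))
    introns <- if (n_ex > 1) sample(20:200, n_ex - 1, replace = TRUE) else integer()
    span <- cds_len + sum(introns)
    gap <- sample(50:300, 1)
    start <- cursor + gap
    if (start + span - 1L > genome_length)
      stop("infeasible packing: genome too short for ", n_genes, " genes",
           call. = FALSE)
    strand <- sample(c("+", "-"), 1)
    orf <- random_orf(n_cod)
    placed <- if (strand == "+") orf else revcomp(orf)
    exons <- matrix(NA_real_, n_ex, 2)
    p <- start
    off <- 0L
    for (e in seq_len(n_ex)) {
      exons[e, ] <- c(p - 1L, p - 1L + ex_lens[e])  # 0-based half-open
      seq_chars[p:(p + ex_lens[e] - 1L)] <-
        strsplit(substr(placed, off + 1L, off + ex_lens[e]), "")[[1]]
      off <- off + ex_lens[e]
      p <- p + ex_lens[e] + if (e < n_ex) introns[e] else 0L
    }
    cursor <- start + span
    cds_list[[g]] <- cds_model(sprintf("gene%02d", g), chrom, strand, exons)
  }
  genome <- stats::setNames(list(paste(seq_chars, collapse = "")), chrom)

  n_ns <- round(ns_ratio * n_syn)
  n_sg <- round(stop_gain_share * n_ns)
  targets <- c(rep("synonymous", n_syn), rep("stop_gain", n_sg),
               rep("missense", n_ns - n_sg))
  used_pos <- integer()
  vars <- list()
  for (tgt in targets) {
    found <- FALSE
    for (try in seq_len(10000)) {
      cds <- cds_list[[sample(length(cds_list), 1)]]
      n_cod_g <- cds_length(cds) %/% 3
      ci <- sample(2:(n_cod_g - 1), 1)  # internal codon: never start/stop
      gpos <- cds_genomic_positions(cds)
      codon_c <- (ci - 1L) * 3L + 1:3
      codon <- paste(vapply(gpos[codon_c] + 1L, function(pp) {
        b <- seq_chars[pp]
        if (cds$strand == "-") unname(comp_base[b]) else b
      }, character(1)), collapse = "")
      cp <- sample(1:3, 1)
      g1 <- gpos[codon_c[cp]] + 1L  # 1-based genomic position
      if (g1 %in% used_pos) next
      ref_coding <- substr(codon, cp, cp)
      for (alt_coding in sample(setdiff(bases, ref_coding))) {
        alt_codon <- codon
        substr(alt_codon, cp, cp) <- alt_coding
        aa0 <- GEN_CODE[[codon]]
        aa1 <- GEN_CODE[[alt_codon]]
        eff <- if (aa0 != "*" && aa1 == "*") "stop_gain"
               else if (aa0 == aa1) "synonymous"
               else if (aa0 == "*") "stop_loss"
               else "missense"
        if (eff == tgt) {
          ref_g <- seq_chars[g1]
          alt_g <- if (cds$strand == "-") unname(comp_base[alt_coding])
                   else alt_coding
          vars[[length(vars) + 1]] <- data.frame(
            chrom = chrom, pos = g1, ref = ref_g, alt = alt_g,
            gene_id = cds$gene_id, true_effect = tgt,
            stringsAsFactors = FALSE)
          used_pos <- c(used_pos, g1)
          found <- TRUE
          break
        }
      }
      if (found) break
    }
    if (!found)
      stop("could not place a ", tgt, " implant", call. = FALSE)
  }
  variants <- if (length(vars)) do.call(rbind, vars)
              else data.frame(chrom = character(), pos = integer(),
                              ref = character(), alt = character(),
                              gene_id = character(), true_effect = character(),
                              stringsAsFactors = FALSE)
  variants <- variants[order(variants$pos), , drop = FALSE]
  rownames(variants) <- NULL
  structure(list(genome = genome, cds_list = cds_list, variants = variants),
            class = "cds_landscape")
}

#' Genotype matrix of implanted variants for a synthetic diploid
#'
#' Represents every implanted variant as a heterozygous genotype in one
#' synthetic individual (plus an optional homozygous-reference companion),
#' ready for [annotate_effects()] and [ns_s_ratio()].
#'
#' @param landscape a `cds_landscape`.
#' @param sample_ids ids of the synthetic individuals (first one carries
#'   all variants heterozygously, the rest are hom-ref).
#' @return A [genotype_matrix()].
#' @export
landscape_genotypes <- function(landscape, sample_ids = c("sim1", "sim2")) {
  v <- landscape$variants
  gt <- matrix(0L, nrow(v), length(sample_ids))
  gt[, 1] <- 1L
  genotype_matrix(v$chrom, v$pos, v$ref, v$alt, gt, sample_ids,
                  anc = v$ref)
}
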