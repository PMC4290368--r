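#' Read a minimal VCF subset into a genotype matrix
#'
#' Parses a VCF (via \pkg{vcfR}) and keeps biallelic SNP records with a GT
#' field.  Multiallelic records and indels are skipped; the number skipped is
#' reported with a message and attached as attribute `n_skipped`.  Phased and
#' unphased genotype separators are both accepted.  If `anc_info_key` is
#' given, the ancestral allele is read from that INFO key (e.g. `AA=G`).
#'
#' @param path path to a VCF file (plain text or gzipped).
#' @param anc_info_key optional INFO key holding the ancestral allele.
#' @return A [genotype_matrix()] with attribute `n_skipped`.
#' @export
read_vcf_subset <- function(path, anc_info_key = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  gtm <- v@gt
  if (nrow(fix) == 0) {
    samples <- if (!is.null(gtm) && ncol(gtm) > 1) colnames(gtm)[-1] else character()
    out <- genotype_matrix(character(), integer(), character(), character(),
                           matrix(integer(), 0, length(samples)), samples)
    attr(out, "n_skipped") <- 0L
    return(out)
  }
  if (is.null(gtm) || ncol(gtm) < 2)
    stop("VCF has no genotype (FORMAT/sample) columns", call. = FALSE)
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  snp <- !is.na(alt) & nchar(ref) == 1 & nchar(alt) == 1 &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_skipped <- sum(!snp)
  if (n_skipped > 0)
    message(n_skipped, " multiallelic/indel record(s) skipped")
  has_gt <- vapply(strsplit(gtm[, "FORMAT"], ":", fixed = TRUE),
                   function(f) "GT" %in% f, logical(1))
  if (any(!has_gt & snp))
    stop("record without GT format field at ",
         fix[which(!has_gt & snp)[1], "CHROM"], ":",
         fix[which(!has_gt & snp)[1], "POS"], call. = FALSE)
  fix <- fix[snp, , drop = FALSE]
  gt_raw <- vcfR::extract.gt(v, element = "GT")[snp, , drop = FALSE]
  code <- function(g) {
    g <- gsub("|", "/", g, fixed = TRUE)
    out <- rep(NA_integer_, length(g))
    out[g %in% c("0/0")] <- 0L
    out[g %in% c("0/1", "1/0")] <- 1L
    out[g %in% c("1/1")] <- 2L
    out
  }
  gt <- apply(gt_raw, 2, code)
  if (!is.matrix(gt)) gt <- matrix(gt, nrow = sum(snp),
                                   dimnames = list(NULL, colnames(gt_raw)))
  anc <- NULL
  if (!is.null(anc_info_key)) {
    aa <- vcfR::extract.info(v, element = anc_info_key)[snp]
    anc <- ifelse(aa %in% c("A", "C", "G", "T"), aa, NA_character_)
  }
  out <- genotype_matrix(fix[, "CHROM"], as.integer(fix[, "POS"]),
                         fix[, "REF"], fix[, "ALT"], gt,
                         colnames(gt_raw), anc = anc)
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Write a genotype matrix as a minimal VCF
#'
#' Emits CHROM, POS, ID, REF, ALT, QUAL, FILTER, INFO, FORMAT(GT) and one
#' genotype column per sample.  The ancestral allele, where known, is written
#' as `AA=` in INFO so that [read_vcf_subset()] round-trips it.
#'
#' @param gm a [genotype_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf_subset <- function(gm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", gm$sample_ids), collapse = "\t")),
             con)
  if (n_sites(gm) > 0) {
    gt_str <- matrix(c("0/0", "0/1", "1/1")[gm$gt + 1L], nrow = n_sites(gm))
    gt_str[is.na(gt_str)] <- "./."
    info <- ifelse(is.na(gm$anc), ".", paste0("AA=", gm$anc))
    body <- cbind(gm$chrom, gm$pos, ".", gm$ref, gm$alt, ".", "PASS",
                  info, "GT", gt_str)
    writeLines(apply(body, 1, paste, collapse = "\t"), con)
  }
  invisible(path)
}
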