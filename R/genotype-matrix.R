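#' Biallelic SNP genotype matrix
#'
#' The central container for resequencing-derived SNP calls: `m` biallelic
#' sites by `n` diploid individuals.  Genotypes are coded as the count of the
#' alternate allele (0 = hom-ref, 1 = het, 2 = hom-alt, `NA` = missing).
#' Positions follow the VCF convention (1-based); all windowed statistics
#' convert to 0-based half-open coordinates at a single point
#' ([assign_windows()]).
#'
#' @param chrom character vector of chromosome/scaffold labels, one per site.
#' @param pos integer vector of 1-based positions, strictly increasing within
#'   each chromosome.
#' @param ref,alt single-base reference and alternate alleles per site.
#' @param gt integer matrix (`m` sites x `n` samples) of alt-allele dosages
#'   in `{0, 1, 2, NA}`.
#' @param sample_ids character vector of `n` unique sample identifiers.
#' @param anc optional per-site ancestral allele (must equal `ref` or `alt`
#'   where non-missing), e.g. inferred from an outgroup reference.
#'
#' @return An object of class `genotype_matrix`.
#' @examples
#' gm <- genotype_matrix(
#'   chrom = c("chr1", "chr1"), pos = c(100L, 200L),
#'   ref = c("A", "C"), alt = c("G", "T"),
#'   gt = matrix(c(0L, 1L, 1L, 2L), nrow = 2),
#'   sample_ids = c("s1", "s2")
#' )
#' n_sites(gm)
#' @export
genotype_matrix <- function(chrom, pos, ref, alt, gt, sample_ids, anc = NULL) {
  m <- length(chrom)
  gt <- matrix(as.integer(gt), nrow = m, ncol = length(sample_ids),
               dimnames = list(NULL, sample_ids))
  obj <- structure(
    list(chrom = as.character(chrom), pos = as.integer(pos),
         ref = as.character(ref), alt = as.character(alt),
         anc = if (is.null(anc)) rep(NA_character_, m) else as.character(anc),
         gt = gt, sample_ids = as.character(sample_ids)),
    class = "genotype_matrix"
  )
  validate_genotype_matrix(obj)
}

validate_genotype_matrix <- function(x) {
  m <- length(x$chrom)
  lens <- c(length(x$pos), length(x$ref), length(x$alt), length(x$anc))
  if (any(lens != m))
    stop("per-site fields have unequal lengths", call. = FALSE)
  if (nrow(x$gt) != m || ncol(x$gt) != length(x$sample_ids))
    stop("gt matrix must be n_sites x n_samples", call. = FALSE)
  if (anyDuplicated(x$sample_ids))
    stop("duplicated sample ids", call. = FALSE)
  if (m > 0) {
    if (any(x$ref == x$alt))
      stop("alt must differ from ref at every site", call. = FALSE)
    inc <- unlist(tapply(x$pos, factor(x$chrom, levels = unique(x$chrom)),
                         function(p) diff(p) > 0), use.names = FALSE)
    if (length(inc) && !all(inc))
      stop("pos must be strictly increasing within each chromosome",
           call. = FALSE)
    bad_anc <- !is.na(x$anc) & x$anc != x$ref & x$anc != x$alt
    if (any(bad_anc))
      stop("ancestral allele matches neither ref nor alt at site(s) ",
           paste(utils::head(which(bad_anc), 5), collapse = ", "),
           call. = FALSE)
    ok <- is.na(x$gt) | (x$gt >= 0L & x$gt <= 2L)
    if (!all(ok)) stop("genotypes must be 0, 1, 2 or NA", call. = FALSE)
  }
  x
}

#' @rdname genotype_matrix
#' @param x,object a `genotype_matrix`.
#' @param ... ignored.
#' @export
n_sites <- function(x) length(x$chrom)

#' @rdname genotype_matrix
#' @export
n_samples <- function(x) length(x$sample_ids)

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d sites x %d samples (%d with ancestral allele)\n",
              n_sites(x), n_samples(x), sum(!is.na(x$anc))))
  invisible(x)
}

#' Subset a genotype matrix by site
#'
#' @param x a `genotype_matrix`.
#' @param i logical or integer site index.
#' @return A `genotype_matrix` with the selected sites.
#' @export
subset_sites <- function(x, i) {
  genotype_matrix(x$chrom[i], x$pos[i], x$ref[i], x$alt[i],
                  x$gt[i, , drop = FALSE], x$sample_ids, x$anc[i])
}

#' Filter sites by genotype completeness
#'
#' Optional site filter mirroring a minimum-callable-individuals rule (e.g.
#' "at least 6 of 9 individuals genotyped"): keeps sites with at least
#' `min_called` non-missing genotypes.
#'
#' @param x a `genotype_matrix`.
#' @param min_called minimum number of non-missing genotypes per site.
#' @return A filtered `genotype_matrix`.
#' @export
filter_min_called <- function(x, min_called) {
  called <- rowSums(!is.na(x$gt))
  subset_sites(x, called >= min_called)
}

#' Allele read-count fallback from genotypes
#'
#' When per-SNP read counts (AD-style fields) are unavailable, pooled
#' major/minor allele counts are substituted by counting carried alleles
#' across individuals: each hom contributes 2 and each het 1 to its allele.
#' Missing genotypes contribute nothing.  The larger pooled count at a site
#' becomes `n_maj`.
#'
#' @param x a `genotype_matrix`.
#' @return A data frame with columns `chrom`, `pos`, `n_maj`, `n_min`.
#' @export
counts_from_genotypes <- function(x) {
  alt_n <- rowSums(x$gt, na.rm = TRUE)
  ref_n <- 2L * rowSums(!is.na(x$gt)) - alt_n
  data.frame(chrom = x$chrom, pos = x$pos,
             n_maj = pmax(ref_n, alt_n), n_min = pmin(ref_n, alt_n),
             stringsAsFactors = FALSE)
}
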