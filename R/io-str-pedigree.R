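#' Diploid STR genotype table
#'
#' Unordered pairs of allele values (repeat counts, or fragment lengths when
#' a locus carries an `offset`) per individual per locus.  Missingness is
#' explicit (`NA`), never encoded as 0.
#'
#' @param sample_ids character vector of unique individual ids.
#' @param locus_ids character vector of unique locus ids.
#' @param unit_size integer repeat-unit size per locus, each in 2..6.
#' @param a1,a2 numeric matrices (samples x loci) holding the two alleles of
#'   each genotype; an individual is missing at a locus iff both are `NA`.
#' @return An object of class `str_genotype_table`.
#' @export
str_genotype_table <- function(sample_ids, locus_ids, unit_size, a1, a2) {
  sample_ids <- as.character(sample_ids)
  locus_ids <- as.character(locus_ids)
  if (anyDuplicated(sample_ids)) stop("duplicated sample id", call. = FALSE)
  if (anyDuplicated(locus_ids)) stop("duplicated locus id", call. = FALSE)
  if (!all(unit_size %in% 2:6))
    stop("unit_size must be in 2..6", call. = FALSE)
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  dimnames(a1) <- dimnames(a2) <- list(sample_ids, locus_ids)
  if (any(c(a1, a2) <= 0, na.rm = TRUE))
    stop("allele values must be positive (missing is NA, never 0)",
         call. = FALSE)
  if (any(xor(is.na(a1), is.na(a2))))
    stop("half-missing genotypes not allowed: both alleles or neither",
         call. = FALSE)
  structure(list(sample_ids = sample_ids, locus_ids = locus_ids,
                 unit_size = stats::setNames(as.integer(unit_size), locus_ids),
                 a1 = a1, a2 = a2),
            class = "str_genotype_table")
}

#' @export
print.str_genotype_table <- function(x, ...) {
  cat(sprintf("str_genotype_table: %d individuals x %d loci (unit sizes %s)\n",
              length(x$sample_ids), length(x$locus_ids),
              paste(sort(unique(x$unit_size)), collapse = ",")))
  invisible(x)
}

#' Read an STR genotype TSV
#'
#' Expected layout: a header line `sample<TAB>locus1<TAB>locus2...`, a
#' metadata line whose first field is `unit_size` giving the repeat-unit
#' size per locus, then one row per individual with genotypes written
#' `a/b` (unordered) or `.` for missing.
#'
#' @param path TSV path.
#' @return An [str_genotype_table()].
#' @export
read_str_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  hdr <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  loci <- hdr[-1]
  meta <- strsplit(lines[[2]], "\t", fixed = TRUE)[[1]]
  if (meta[1] != "unit_size")
    stop("second line must be the unit_size metadata row", call. = FALSE)
  unit <- as.integer(meta[-1])
  rows <- strsplit(lines[-(1:2)], "\t", fixed = TRUE)
  ids <- vapply(rows, `[[`, character(1), 1)
  if (anyDuplicated(ids))
    stop("duplicated sample id: ", ids[duplicated(ids)][1], call. = FALSE)
  n <- length(ids); L <- length(loci)
  a1 <- matrix(NA_real_, n, L); a2 <- matrix(NA_real_, n, L)
  for (i in seq_len(n)) {
    fields <- rows[[i]][-1]
    if (length(fields) != L)
      stop("row ", ids[i], " has ", length(fields), " genotypes, expected ",
           L, call. = FALSE)
    for (j in seq_len(L)) {
      f <- fields[j]
      if (f == "." || f == "./.") next
      ab <- strsplit(f, "/", fixed = TRUE)[[1]]
      vals <- suppressWarnings(as.numeric(ab))
      if (length(vals) != 2 || anyNA(vals) || any(vals != round(vals)))
        stop("non-integer allele at row ", ids[i], ", locus ", loci[j],
             call. = FALSE)
      a1[i, j] <- vals[1]; a2[i, j] <- vals[2]
    }
  }
  str_genotype_table(ids, loci, unit, a1, a2)
}

#' Write an STR genotype table in the format read by [read_str_table()]
#'
#' @param tbl an [str_genotype_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_str_table <- function(tbl, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("sample", tbl$locus_ids), collapse = "\t"), con)
  writeLines(paste(c("unit_size", tbl$unit_size), collapse = "\t"), con)
  for (i in seq_along(tbl$sample_ids)) {
    g <- ifelse(is.na(tbl$a1[i, ]), ".",
                paste0(tbl$a1[i, ], "/", tbl$a2[i, ]))
    writeLines(paste(c(tbl$sample_ids[i], g), collapse = "\t"), con)
  }
  invisible(path)
}

#' Pedigree table
#'
#' @param individual_id character ids, unique.
#' @param sire_id,dam_id parent ids or `NA` for founders; sires must be ZZ
#'   and dams ZW where sexes are known.
#' @param sex `"ZZ"`, `"ZW"` or `"unknown"` (birds: males ZZ, females ZW).
#' @param year integer cohort label (year or generation index).
#' @return A data frame of class `pedigree`.
#' @export
pedigree <- function(individual_id, sire_id, dam_id, sex, year) {
  df <- data.frame(individual_id = as.character(individual_id),
                   sire_id = as.character(sire_id),
                   dam_id = as.character(dam_id),
                   sex = as.character(sex),
                   year = as.integer(year),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$individual_id))
    stop("duplicated individual id", call. = FALSE)
  if (!all(df$sex %in% c("ZZ", "ZW", "unknown")))
    stop("sex must be ZZ, ZW or unknown", call. = FALSE)
  sx <- stats::setNames(df$sex, df$individual_id)
  known_sire <- df$sire_id[!is.na(df$sire_id) & df$sire_id %in% names(sx)]
  if (any(sx[known_sire] == "ZW")) stop("a sire is ZW", call. = FALSE)
  known_dam <- df$dam_id[!is.na(df$dam_id) & df$dam_id %in% names(sx)]
  if (any(sx[known_dam] == "ZZ")) stop("a dam is ZZ", call. = FALSE)
  # acyclicity: iteratively strip individuals whose parents are all resolved
  remaining <- df$individual_id
  resolved <- character()
  repeat {
    free <- remaining[vapply(remaining, function(id) {
      r <- df[df$individual_id == id, ]
      (is.na(r$sire_id) || r$sire_id %in% resolved || !(r$sire_id %in% df$individual_id)) &&
        (is.na(r$dam_id) || r$dam_id %in% resolved || !(r$dam_id %in% df$individual_id))
    }, logical(1))]
    if (length(free) == 0) break
    resolved <- c(resolved, free)
    remaining <- setdiff(remaining, free)
  }
  if (length(remaining) > 0)
    stop("pedigree contains a cycle involving: ",
         paste(utils::head(remaining, 3), collapse = ", "), call. = FALSE)
  class(df) <- c("pedigree", "data.frame")
  df
}

#' Read / write pedigree TSV (individual, sire, dam, sex, year)
#'
#' @param path TSV path with header `individual_id sire_id dam_id sex year`;
#'   missing parents written `.`.
#' @return [read_pedigree()] returns a `pedigree`; [write_pedigree()] its
#'   `path`, invisibly.
#' @export
read_pedigree <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, na.strings = ".")
  pedigree(df$individual_id, df$sire_id, df$dam_id, df$sex, df$year)
}

#' @rdname read_pedigree
#' @param ped a `pedigree`.
#' @export
write_pedigree <- function(ped, path) {
  out <- ped
  out$sire_id[is.na(out$sire_id)] <- "."
  out$dam_id[is.na(out$dam_id)] <- "."
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
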