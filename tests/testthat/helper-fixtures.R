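# shared fixtures, all generated in code

random_gm <- function(n_sites = 20, n_samples = 4, seed = 1,
                      missing_rate = 0.1, with_anc = FALSE) {
  set.seed(seed)
  pos <- sort(sample.int(1e5, n_sites))
  ref <- sample(c("A", "C", "G", "T"), n_sites, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                character(1))
  gt <- matrix(sample(0:2, n_sites * n_samples, replace = TRUE),
               n_sites, n_samples)
  gt[stats::runif(length(gt)) < missing_rate] <- NA_integer_
  anc <- if (with_anc) ifelse(stats::runif(n_sites) < 0.5, ref, alt) else NULL
  genotype_matrix(rep("chr1", n_sites), pos, ref, alt, gt,
                  sprintf("s%02d", seq_len(n_samples)), anc = anc)
}

write_test_vcf <- function(lines, path = tempfile(fileext = ".vcf")) {
  header <- c("##fileformat=VCFv4.2",
              paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                    "INFO", "FORMAT", "ind1", sep = "\t"))
  writeLines(c(header, lines), path)
  path
}

# genotype vectors for a diploid sample drawn from given two-locus
# haplotype frequencies (named AB, Ab, aB, ab); returns phased truth too
draw_two_locus_pop <- function(n, freqs, seed = 1) {
  set.seed(seed)
  haps <- sample(names(freqs), 2 * n, replace = TRUE, prob = freqs)
  h1 <- haps[seq_len(n)]
  h2 <- haps[n + seq_len(n)]
  ga <- (substr(h1, 1, 1) == "a") + (substr(h2, 1, 1) == "a")
  gb <- (substr(h1, 2, 2) == "b") + (substr(h2, 2, 2) == "b")
  list(ga = ga, gb = gb,
       realized = table(factor(haps, c("AB", "Ab", "aB", "ab"))) / (2 * n))
}

# brute-force STR scanner: for each unit size and start, extend the exact
# tandem run; keep left-maximal runs meeting length/repeat/primitivity rules
brute_force_strs <- function(sequence, unit_sizes = 2:6, min_total_length = 8) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  n <- length(chars)
  res <- list()
  for (u in unit_sizes) {
    i <- 1
    while (i + 2 * u - 1 <= n) {
      j <- i + u
      while (j <= n && chars[j] == chars[j - u] &&
             chars[j] != "N" && chars[j - u] != "N") j <- j + 1
      len <- j - i
      if (len >= u + u && len >= min_total_length &&
          !any(chars[i:(i + 2 * u - 1)] == "N")) {
        left_max <- i == 1 || chars[i - 1] == "N" || chars[i - 1 + u] == "N" ||
          chars[i - 1] != chars[i - 1 + u]
        region <- chars[i:(i + len - 1)]
        primitive <- TRUE
        for (v in seq_len(u - 1)) {
          if (all(region[(v + 1):len] == region[1:(len - v)])) {
            primitive <- FALSE; break
          }
        }
        if (left_max && primitive) {
          res[[length(res) + 1]] <- data.frame(
            start = i - 1, end = i - 1 + len, unit_size = u,
            n_repeats = len %/% u,
            unit = paste(region[1:u], collapse = ""),
            stringsAsFactors = FALSE)
        }
      }
      i <- i + 1
    }
  }
  if (!length(res))
    return(data.frame(start = integer(), end = integer(),
                      unit_size = integer(), n_repeats = integer(),
                      unit = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  out <- out[order(out$start, out$unit_size), , drop = FALSE]
  rownames(out) <- NULL
  out
}

random_dna <- function(n, seed = 1, with_n = FALSE) {
  set.seed(seed)
  alphabet <- if (with_n) c("A", "C", "G", "T", "N") else c("A", "C", "G", "T")
  paste(sample(alphabet, n, replace = TRUE,
               prob = if (with_n) c(rep(0.24, 4), 0.04) else NULL),
        collapse = "")
}
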