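#' Simulate a managed-recovery pedigree
#'
#' Emulates a captive-breeding programme founded by a handful of breeding
#' pairs.  In `deterministic` mode the breeding pool each season is every
#' individual recorded so far; pairs are formed male-female in id order,
#' each pair produces exactly `offspring_per_pair` offspring and offspring
#' sexes alternate, so the census doubles each season when
#' `offspring_per_pair = 2` (founding 2 pairs gives cohorts 4, 4, 8, 16 over
#' three seasons).  In `random` mode only the newest generation breeds, in
#' randomly shuffled monogamous pairs, with Poisson(`mean_offspring`)
#' offspring per pair and Bernoulli(1/2) sexes; a generation with no
#' possible pair or no offspring yields an explicit extinction result, not
#' an error.
#'
#' @param founder_pairs number of founding breeding pairs (>= 1).
#' @param generations breeding seasons to simulate.
#' @param offspring_per_pair offspring per pair in deterministic mode.
#' @param mode `"deterministic"` or `"random"`.
#' @param mean_offspring Poisson mean per pair in random mode.
#' @param seed RNG seed (random mode).
#' @return List of class `pedigree_sim`: `ped` (a [pedigree()]), `extinct`
#'   (logical), `extinct_at` (generation, or `NA`).
#' @export
simulate_pedigree <- function(founder_pairs = 2, generations = 3,
                              offspring_per_pair = 2,
                              mode = c("deterministic", "random"),
                              mean_offspring = 2, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(founder_pairs >= 1, generations >= 0)
  set.seed(seed)
  id <- sprintf("F%02d", seq_len(2 * founder_pairs))
  df <- data.frame(individual_id = id, sire_id = NA_character_,
                   dam_id = NA_character_,
                   sex = rep(c("ZZ", "ZW"), founder_pairs),
                   year = 0L, stringsAsFactors = FALSE)
  extinct <- FALSE; extinct_at <- NA_integer_
  counter <- 0L
  for (g in seq_len(generations)) {
    pool <- if (mode == "deterministic") df else df[df$year == g - 1L, ]
    males <- pool$individual_id[pool$sex == "ZZ"]
    females <- pool$individual_id[pool$sex == "ZW"]
    if (mode == "random") {
      males <- sample(males)
      females <- sample(females)
    }
    n_pairs <- min(length(males), length(females))
    if (n_pairs == 0) { extinct <- TRUE; extinct_at <- g; break }
    kids <- list()
    for (k in seq_len(n_pairs)) {
      n_off <- if (mode == "deterministic") offspring_per_pair
               else stats::rpois(1, mean_offspring)
      if (n_off == 0) next
      counter_seq <- counter + seq_len(n_off)
      counter <- counter + n_off
      sexes <- if (mode == "deterministic")
        ifelse(counter_seq %% 2 == 1, "ZZ", "ZW") else
        sample(c("ZZ", "ZW"), n_off, replace = TRUE)
      kids[[k]] <- data.frame(
        individual_id = sprintf("G%d_%03d", g, counter_seq),
        sire_id = males[k], dam_id = females[k],
        sex = sexes, year = g, stringsAsFactors = FALSE)
    }
    if (!length(kids)) { extinct <- TRUE; extinct_at <- g; break }
    df <- rbind(df, do.call(rbind, kids))
  }
  ped <- pedigree(df$individual_id, df$sire_id, df$dam_id, df$sex, df$year)
  structure(list(ped = ped, extinct = extinct, extinct_at = extinct_at),
            class = "pedigree_sim")
}

#' @export
print.pedigree_sim <- function(x, ...) {
  cat(sprintf("pedigree_sim: %d individuals over %d cohorts%s\n",
              nrow(x$ped), length(unique(x$ped$year)),
              if (x$extinct) sprintf(" (EXTINCT at generation %d)", x$extinct_at)
              else ""))
  invisible(x)
}

#' Simulate STR genotypes down a pedigree (stepwise mutation model)
#'
#' Founder alleles are drawn from `founder_alleles` (uniform by default);
#' each meiosis transmits one of the parent's two alleles and mutates it
#' with probability `mu` by a single repeat unit, up or down with equal
#' probability (symmetric single-step SMM).  A step that would reach 0
#' repeats is reflected upward (+1 instead).  Individuals with a missing
#' parent draw that allele from the founder distribution.
#'
#' @param ped a [pedigree()] (or `pedigree_sim`).
#' @param n_loci number of autosomal STR loci.
#' @param unit_sizes repeat-unit sizes, recycled over loci (default 4).
#' @param mu per-meiosis per-locus mutation rate, in `[0, 0.1]`.
#' @param founder_alleles integer repeat counts founders draw from.
#' @param seed RNG seed.
#' @return An [str_genotype_table()] with attribute `truth` (data frame of
#'   mutation events: individual, locus, from, to).
#' @export
simulate_str_smm <- function(ped, n_loci = 22, unit_sizes = 4, mu = 5e-3,
                             founder_alleles = 8:15, seed = 1L) {
  if (inherits(ped, "pedigree_sim")) ped <- ped$ped
  stopifnot(mu >= 0, mu <= 0.1)
  set.seed(seed)
  loci <- sprintf("STR%02d", seq_len(n_loci))
  unit <- rep(unit_sizes, length.out = n_loci)
  n <- nrow(ped)
  a1 <- matrix(NA_real_, n, n_loci, dimnames = list(ped$individual_id, loci))
  a2 <- a1
  events <- list()
  draw_founder <- function() {
    if (length(founder_alleles) == 1) founder_alleles
    else sample(founder_alleles, 1)
  }
  mutate <- function(allele, who, locus) {
    if (stats::runif(1) >= mu) return(allele)
    step <- sample(c(-1, 1), 1)
    new <- allele + step
    if (new < 1) new <- allele + 1
    events[[length(events) + 1]] <<- data.frame(
      individual = who, locus = locus, from = allele, to = new,
      stringsAsFactors = FALSE)
    new
  }
  order_idx <- order(ped$year)  # parents precede offspring by cohort
  for (i in order_idx) {
    who <- ped$individual_id[i]
    for (j in seq_len(n_loci)) {
      from_parent <- function(pid) {
        if (is.na(pid) || !(pid %in% rownames(a1)) || is.na(a1[pid, j]))
          return(draw_founder())
        mutate(sample(c(a1[pid, j], a2[pid, j]), 1), who, loci[j])
      }
      a1[who, j] <- from_parent(ped$sire_id[i])
      a2[who, j] <- from_parent(ped$dam_id[i])
    }
  }
  tbl <- str_genotype_table(ped$individual_id, loci, unit, a1, a2)
  attr(tbl, "truth") <- if (length(events)) do.call(rbind, events)
                        else data.frame(individual = character(),
                                        locus = character(),
                                        from = numeric(), to = numeric())
  tbl
}

#' Simulate a W-linked sex-marker profile
#'
#' The marker is transmitted dam-to-daughter: ZW individuals carry the
#' Z-length allele plus the W-specific `z_length + insertion` allele, ZZ
#' individuals two Z-length alleles, unknown-sex individuals are missing.
#'
#' @param ped a [pedigree()] (or `pedigree_sim`).
#' @param z_length Z-allele fragment length in bp.
#' @param insertion W-specific insertion size (default 31 bp).
#' @return Data frame: `individual_id`, `a1`, `a2`, `true_sex`.
#' @export
simulate_w_marker <- function(ped, z_length = 180, insertion = 31) {
  if (inherits(ped, "pedigree_sim")) ped <- ped$ped
  a1 <- rep(z_length, nrow(ped))
  a2 <- ifelse(ped$sex == "ZW", z_length + insertion, z_length)
  a1[ped$sex == "unknown"] <- NA_real_
  a2[ped$sex == "unknown"] <- NA_real_
  data.frame(individual_id = ped$individual_id, a1 = a1, a2 = a2,
             true_sex = ped$sex, stringsAsFactors = FALSE)
}
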