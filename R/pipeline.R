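#' Run the full analysis pipeline
#'
#' Orchestrates an end-to-end run over either supplied input files or a
#' simulated scenario: data acquisition, per-individual diversity and
#' Watterson's theta, the windowed Hp/ZHp fixation scan, coding-effect and
#' NS/S analysis, LD decay, FST, and the forensic STR panel.  Stages run in
#' dependency order; the first failing stage aborts the run with an error
#' naming it.  Re-running with an identical config reproduces identical
#' outputs.
#'
#' @param config a list, or the path to a YAML file.  Top-level keys:
#'   \describe{
#'     \item{scenario}{simulation settings: `founder_pairs`, `generations`,
#'       `wf` (arguments to [demography_config()]), `str` (arguments to
#'       [simulate_str_smm()]), `cds` (arguments to
#'       [generate_cds_landscape()]).  Mutually exclusive with `inputs`.}
#'     \item{inputs}{paths: `vcf`, `str`, `pedigree` (any subset).}
#'     \item{params}{`window_width` (default 5e5), `zhp_q` (default 0.01),
#'       `min_snps_per_window` (default 10), `callable_length`, `ld` (list
#'       passed to [ld_config()]), `subpops` (named vector sample -> label).}
#'     \item{outdir}{output directory for TSV/BED files (optional).}
#'     \item{seed}{integer seed controlling all randomness.}
#'   }
#' @return A list of class `pipeline_report`: one entry per executed stage,
#'   plus `provenance` (seed, config digest, package version).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  has_inputs <- !is.null(config$inputs)
  has_scenario <- !is.null(config$scenario)
  if (has_inputs == has_scenario)
    stop("stage validate failed: exactly one of inputs/scenario must be set",
         call. = FALSE)
  if (has_inputs) {
    missing <- unlist(config$inputs)[!file.exists(unlist(config$inputs))]
    if (length(missing))
      stop("stage validate failed: missing input file(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
  }
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  par <- config$params
  zhp_q <- par$zhp_q %||% 0.01
  min_snps <- par$min_snps_per_window %||% 10
  report <- list()
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage ", name, " failed: ", conditionMessage(e), call. = FALSE))
  }

  # -- acquire ---------------------------------------------------------
  gm <- str_tbl <- ped <- landscape <- NULL
  L <- par$callable_length %||% NA
  run_stage("acquire", {
    if (has_scenario) {
      sc <- config$scenario
      wf_args <- sc$wf %||% list()
      if (is.null(wf_args$epochs))
        wf_args$epochs <- data.frame(N = 50, duration = 20)
      else wf_args$epochs <- as.data.frame(wf_args$epochs)
      wf_args$seed <- seed
      if (is.null(wf_args$init_sites)) wf_args$init_sites <- 2000
      if (length(wf_args$sample_times) == 0) {
        wf_args$sample_times <- sum(wf_args$epochs$duration)
        wf_args$sample_sizes <- min(10, min(wf_args$epochs$N))
      }
      sim <- simulate_wright_fisher(do.call(demography_config, wf_args))
      gm <- sim$samples[[length(sim$samples)]]$gm
      if (is.na(L)) L <- wf_args$L %||% 1e6
      psim <- simulate_pedigree(
        founder_pairs = sc$founder_pairs %||% 2,
        generations = sc$generations %||% 3, seed = seed + 1L)
      ped <- psim$ped
      str_args <- sc$str %||% list()
      str_args$ped <- ped
      str_args$seed <- seed + 2L
      str_tbl <- do.call(simulate_str_smm, str_args)
      cds_args <- sc$cds %||% list()
      cds_args$seed <- seed + 3L
      landscape <- do.call(generate_cds_landscape, cds_args)
    } else {
      if (!is.null(config$inputs$vcf)) gm <- read_vcf_subset(config$inputs$vcf)
      if (!is.null(config$inputs$str)) str_tbl <- read_str_table(config$inputs$str)
      if (!is.null(config$inputs$pedigree)) ped <- read_pedigree(config$inputs$pedigree)
      if (is.na(L) && !is.null(gm) && n_sites(gm) > 0) L <- max(gm$pos)
    }
  })

  # -- diversity + scan ------------------------------------------------
  if (!is.null(gm) && n_sites(gm) > 0) {
    report$diversity <- run_stage("diversity", {
      het <- vapply(gm$sample_ids, function(s)
        individual_heterozygosity(gm, s, L), numeric(1))
      K <- sum(apply(gm$gt, 1, function(g) {
        v <- g[!is.na(g)]
        length(v) > 0 && any(v > 0) && any(v < 2)
      }))
      th <- watterson_theta(K, 2 * n_samples(gm), L)
      list(stage = "diversity",
           het_per_sample = data.frame(sample = gm$sample_ids, het = het),
           theta = th)
    })
    report$scan <- run_stage("scan", {
      chrlen <- vapply(split(gm$pos, gm$chrom), max, numeric(1))
      chrlen[] <- pmax(chrlen, L)
      # default window width: 500 kb on real data, 1/20 of the simulated
      # genome in scenario mode so the scan has a usable window count
      width <- par$window_width %||%
        if (has_scenario) max(1000, floor(L / 20)) else 5e5
      wins <- make_windows(chrlen, width = width)
      hpw <- window_hp(counts_from_genotypes(gm), wins, min_snps = min_snps)
      hpw <- call_sweep_windows(zhp_transform(hpw),
                                threshold = normal_quantile(zhp_q))
      list(stage = "scan", windows = hpw, summary = attr(hpw, "summary"))
    })
    report$ld <- run_stage("ld", {
      set.seed(seed + 10L)
      ld_args <- par$ld %||% list()
      # keep end-to-end runs light: modest pair subsample unless overridden
      if (is.null(ld_args$max_pairs_per_bin)) ld_args$max_pairs_per_bin <- 200
      cfg <- do.call(ld_config, ld_args)
      curve <- tryCatch(ld_decay_curve(gm, cfg), error = function(e) NULL)
      list(stage = "ld", curve = curve,
           half_max = if (!is.null(curve)) half_max_distance(curve))
    })
    subpops <- par$subpops
    if (is.null(subpops) && has_scenario && n_samples(gm) >= 4) {
      half <- n_samples(gm) %/% 2
      subpops <- stats::setNames(rep(c("p1", "p2"),
                                     c(half, n_samples(gm) - half)),
                                 gm$sample_ids)
    }
    if (!is.null(subpops))
      report$fst <- run_stage("fst", {
        list(stage = "fst",
             fst = weir_cockerham_fst(gm, subpops[gm$sample_ids]))
      })
  }

  # -- coding effects --------------------------------------------------
  if (!is.null(landscape)) {
    report$effects <- run_stage("effects", {
      vg <- landscape_genotypes(landscape)
      eff <- annotate_effects(vg, landscape$cds_list, landscape$genome)
      het_eff <- eff$effect[vg$gt[eff$site, 1] == 1L]
      list(stage = "effects", effects = eff,
           ns_s = ns_s_ratio(het_eff),
           daf = daf_spectrum(vg, class = ifelse(
             eff$effect[match(seq_len(n_sites(vg)), eff$site)] == "synonymous",
             "S", "NS")))
    })
  }

  # -- STR panel -------------------------------------------------------
  if (!is.null(str_tbl)) {
    report$str <- run_stage("str", {
      sums <- lapply(str_tbl$locus_ids, function(lc)
        str_locus_summary(str_tbl, lc))
      panel <- forensic_panel(str_tbl)
      sexes <- NULL
      if (!is.null(ped)) {
        wm <- simulate_w_marker(ped)
        sexes <- data.frame(
          individual_id = wm$individual_id,
          call = vapply(seq_len(nrow(wm)), function(i)
            sex_call(c(wm$a1[i], wm$a2[i]), z_length = 180), character(1)),
          true_sex = wm$true_sex, stringsAsFactors = FALSE)
      }
      list(stage = "str", summaries = sums,
           polymorphic = polymorphic_fraction(sums, min_alleles = 4),
           panel = panel, sex_calls = sexes)
    })
  }

  report$provenance <- list(
    seed = seed,
    config_digest = config_digest(config),
    package_version = as.character(utils::packageVersion("ibispop")))
  # -- write outputs ---------------------------------------------------
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(report$scan))
      write_windows_bed(report$scan$windows,
                        file.path(config$outdir, "hp_windows.bed"))
    if (!is.null(report$diversity))
      utils::write.table(report$diversity$het_per_sample,
                         file.path(config$outdir, "heterozygosity.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(report$str))
      utils::write.table(report$str$panel$per_locus,
                         file.path(config$outdir, "str_panel.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  class(report) <- "pipeline_report"
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_digest <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(paste(deparse(config), collapse = ""), f)
  unname(tools::md5sum(f))
}

#' @export
print.pipeline_report <- function(x, ...) {
  stages <- setdiff(names(x), "provenance")
  cat("pipeline_report with stages:", paste(stages, collapse = ", "), "\n")
  if (!is.null(x$scan))
    cat(sprintf("  scan: %d/%d windows flagged (%.1f%%)\n",
                x$scan$summary$n_flagged, x$scan$summary$n_total,
                x$scan$summary$pct))
  if (!is.null(x$str))
    cat(sprintf("  str: combined PD %.4f, combined PE %.4f\n",
                x$str$panel$combined_pd, x$str$panel$combined_pe))
  invisible(x)
}

#' Compare a per-species statistic between two groups
#'
#' Group means and medians, Welch's two-sample t test, and a seeded
#' permutation test on the mean difference as a distribution-free
#' companion.
#'
#' @param values numeric per-species statistic.
#' @param groups two-level grouping (e.g. endangered-vulnerable vs
#'   least-concern), each level with >= 2 species.
#' @param n_perm permutation count (default 10000).
#' @return List of class `group_comparison`: `summary` (per-group n, mean,
#'   median), `mean_difference` (group1 - group2), `t_statistic`,
#'   `p_welch`, `p_perm`.
#' @export
compare_groups <- function(values, groups, n_perm = 10000) {
  groups <- as.character(groups)
  lev <- unique(groups)
  if (length(lev) != 2) stop("need exactly two groups", call. = FALSE)
  if (any(table(groups) < 2)) stop("each group needs >= 2 values", call. = FALSE)
  x <- values[groups == lev[1]]
  y <- values[groups == lev[2]]
  tt <- stats::t.test(x, y)
  obs <- mean(x) - mean(y)
  perm <- replicate(n_perm, {
    g <- sample(groups)
    mean(values[g == lev[1]]) - mean(values[g == lev[2]])
  })
  p_perm <- (1 + sum(abs(perm) >= abs(obs))) / (n_perm + 1)
  structure(list(
    summary = data.frame(group = lev,
                         n = c(length(x), length(y)),
                         mean = c(mean(x), mean(y)),
                         median = c(stats::median(x), stats::median(y))),
    mean_difference = obs, t_statistic = unname(tt$statistic),
    p_welch = tt$p.value, p_perm = p_perm),
    class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  print(x$summary)
  cat(sprintf("mean difference %.4g; Welch p = %.3g; permutation p = %.3g\n",
              x$mean_difference, x$p_welch, x$p_perm))
  invisible(x)
}
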