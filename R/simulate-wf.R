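#' Demography configuration for the Wright-Fisher simulator
#'
#' Piecewise-constant diploid population sizes, e.g. a severe bottleneck to
#' two breeding pairs followed by managed recovery.  The seed fixes all
#' downstream randomness.
#'
#' @param epochs data frame with columns `N` (diploid size, >= 2) and
#'   `duration` (generations, >= 1), in forward time order.
#' @param mu per-site per-generation mutation rate.
#' @param L genome length in bp.
#' @param recomb_rate per-bp per-generation recombination rate (a single
#'   crossover per gamete at rate `recomb_rate * L`).
#' @param init_sites number of segregating sites in the founder population.
#' @param init_freq founder derived-allele frequency for each initial site
#'   (`"sfs"` draws frequencies from the neutral site-frequency spectrum,
#'   with the number of sites Poisson at its stationary expectation, and
#'   ignores `init_sites`).
#' @param sample_times generations (0 = founders) at which to emit samples.
#' @param sample_sizes diploid individuals per sample time.
#' @param seed integer RNG seed.
#' @return List of class `demography_config`.
#' @export
demography_config <- function(epochs, mu = 0, L = 1e6, recomb_rate = 0,
                              init_sites = 100, init_freq = 0.5,
                              sample_times = integer(),
                              sample_sizes = integer(), seed = 1L) {
  epochs <- as.data.frame(epochs)
  stopifnot(all(c("N", "duration") %in% names(epochs)),
            all(epochs$N >= 2), all(epochs$duration >= 1),
            mu >= 0, L >= 1, recomb_rate >= 0,
            length(sample_times) == length(sample_sizes))
  structure(list(epochs = epochs, mu = mu, L = L,
                 recomb_rate = recomb_rate, init_sites = init_sites,
                 init_freq = init_freq, sample_times = as.integer(sample_times),
                 sample_sizes = as.integer(sample_sizes),
                 seed = as.integer(seed)),
            class = "demography_config")
}

# draw a crossover-recombined gamete set: one row per gamete
wf_gametes <- function(H, parent, pos, L, recomb_rate) {
  n_gam <- length(parent)
  s <- sample(c(0L, 1L), n_gam, replace = TRUE)
  idx1 <- 2L * (parent - 1L) + 1L + s
  idx2 <- 2L * (parent - 1L) + 2L - s
  G <- H[idx1, , drop = FALSE]
  pr <- min(1, recomb_rate * L)
  if (pr > 0 && ncol(H) > 0) {
    cross <- stats::runif(n_gam) < pr
    if (any(cross)) {
      cut <- stats::runif(sum(cross), 0, L)
      right <- outer(cut, pos, `<`)   # sites beyond the crossover point
      Gc <- G[cross, , drop = FALSE]
      G2 <- H[idx2[cross], , drop = FALSE]
      Gc[right] <- G2[right]
      G[cross, ] <- Gc
    }
  }
  G
}

#' Forward-in-time Wright-Fisher simulation
#'
#' Diploid, discrete generations: each offspring receives one (optionally
#' recombined) gamete from each of two parents drawn uniformly at random
#' with replacement (canonical monoecious Wright-Fisher sampling, under
#' which heterozygosity decays exactly as `(1 - 1/(2N))` per generation in
#' expectation).  Mutation follows the infinite-sites model at rate `mu * L` per
#' gamete, each mutation creating a new site at a fresh position with the
#' ancestral state known by construction.  Deterministic under the seed.
#'
#' @param config a [demography_config()].
#' @return List of class `wf_simulation`:
#'   \describe{
#'     \item{samples}{one entry per sample time: `gen`, `gm` (a
#'       [genotype_matrix()] of the sampled individuals over sites still
#'       segregating in the sample... sites are the population's segregating
#'       sites), `haplotypes` (the phased truth, 2 rows per individual).}
#'     \item{traj}{per-generation data frame: `gen`, `sum_het` (sum over
#'       sites of `2pq`), `n_seg` (segregating sites).}
#'     \item{truth}{positions, ref/alt/ancestral alleles of all sites ever
#'       emitted in samples.}
#'   }
#' @export
simulate_wright_fisher <- function(config) {
  set.seed(config$seed)
  ep <- config$epochs
  N <- ep$N[1]
  L <- config$L
  # founder state
  if (identical(config$init_freq, "sfs")) {
    harm <- sum(1 / seq_len(2 * N - 1))
    S <- stats::rpois(1, 4 * N * config$mu * L * harm)
    counts <- sample(seq_len(2 * N - 1), S, replace = TRUE,
                     prob = 1 / seq_len(2 * N - 1))
  } else {
    S <- config$init_sites
    counts <- rep(max(1L, round(2 * N * config$init_freq)), S)
  }
  H <- matrix(0L, 2 * N, S)
  for (j in seq_len(S)) H[sample.int(2 * N, counts[j]), j] <- 1L
  pos <- if (S > 0) sort(sample.int(L, S)) else numeric(0)
  ref <- sample(c("A", "C", "G", "T"), S, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                character(1))
  next_id <- S + 1L
  total_gens <- sum(ep$duration)
  traj <- data.frame(gen = 0:total_gens, sum_het = NA_real_,
                     n_seg = NA_integer_)
  samples <- list()

  record <- function(gen, H, N) {
    p <- colMeans(H)
    traj$sum_het[traj$gen == gen] <<- sum(2 * p * (1 - p))
    traj$n_seg[traj$gen == gen] <<- sum(p > 0 & p < 1)
    k <- match(gen, config$sample_times)
    if (!is.na(k)) {
      ns <- config$sample_sizes[k]
      if (ns > N) stop("sample size ", ns, " exceeds population size ", N,
                       " at generation ", gen, call. = FALSE)
      ind <- sort(sample.int(N, ns))
      hrows <- as.vector(rbind(2L * ind - 1L, 2L * ind))
      Hs <- H[hrows, , drop = FALSE]
      seg <- which(colSums(Hs) > 0)   # sites carried by the sample
      o <- seg[order(pos[seg])]
      gt <- t(Hs[seq(1, nrow(Hs), 2), o, drop = FALSE] +
                Hs[seq(2, nrow(Hs), 2), o, drop = FALSE])
      ids <- sprintf("g%d_i%02d", gen, ind)
      gm <- genotype_matrix(rep("chr1", length(o)), pos[o], ref[o], alt[o],
                            gt, ids, anc = ref[o])
      samples[[length(samples) + 1]] <<- list(
        gen = gen, gm = gm,
        haplotypes = Hs[, o, drop = FALSE], site_index = o)
    }
  }

  record(0L, H, N)
  gen <- 0L
  for (e in seq_len(nrow(ep))) {
    for (g in seq_len(ep$duration[e])) {
      gen <- gen + 1L
      N_next <- if (g == ep$duration[e] && e < nrow(ep)) ep$N[e + 1] else ep$N[e]
      # canonical WF: each gamete draws its parent independently, so the
      # closed-form decay E[2pq] -> 2pq (1 - 1/(2N)) holds exactly
      p1 <- sample.int(N, N_next, replace = TRUE)
      p2 <- sample.int(N, N_next, replace = TRUE)
      G1 <- wf_gametes(H, p1, pos, L, config$recomb_rate)
      G2 <- wf_gametes(H, p2, pos, L, config$recomb_rate)
      H <- matrix(0L, 2 * N_next, max(ncol(G1), 0))
      H[seq(1, 2 * N_next, 2), ] <- G1
      H[seq(2, 2 * N_next, 2), ] <- G2
      N <- N_next
      # new mutations, one carrier gamete each
      if (config$mu > 0) {
        n_mut <- stats::rpois(1, 2 * N * config$mu * L)
        if (n_mut > 0) {
          newp <- sample.int(L, n_mut)
          fresh <- !(newp %in% pos)
          newp <- newp[fresh]
          if (length(newp)) {
            M <- matrix(0L, 2 * N, length(newp))
            M[cbind(sample.int(2 * N, length(newp), replace = TRUE),
                    seq_along(newp))] <- 1L
            H <- cbind(H, M)
            pos <- c(pos, newp)
            nref <- sample(c("A", "C", "G", "T"), length(newp), replace = TRUE)
            ref <- c(ref, nref)
            alt <- c(alt, vapply(nref, function(b)
              sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1)))
          }
        }
      }
      # drop sites lost from the population (fixed sites kept out of
      # heterozygosity by definition but pruned too: they are invariant)
      p <- colMeans(H)
      keep <- p > 0 & p < 1
      H <- H[, keep, drop = FALSE]
      pos <- pos[keep]; ref <- ref[keep]; alt <- alt[keep]
      record(gen, H, N)
    }
  }
  structure(list(samples = samples, traj = traj,
                 truth = list(pos = pos, ref = ref, alt = alt, anc = ref),
                 config = config),
            class = "wf_simulation")
}

#' Closed-form drift expectation for heterozygosity decay
#'
#' `H_t = H_0 * (1 - 1/(2N))^t`: the expected erosion of heterozygosity per
#' generation in a Wright-Fisher population of constant diploid size N.
#'
#' @param h0 initial heterozygosity.
#' @param N diploid population size.
#' @param t generations.
#' @return Expected heterozygosity at generation `t`.
#' @export
drift_decay_expectation <- function(h0, N, t) h0 * (1 - 1 / (2 * N))^t
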