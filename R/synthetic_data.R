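#' Simulation configuration
#'
#' The default design mirrors a four-breed resequencing panel: a focal
#' population of 8 diploids (`Yanbian`), a sister population of 17
#' (`Hanwoo`) and two outgroups of 10 each (`Holstein`, `Angus`), all
#' drifted from a shared ancestor under the Balding-Nichols model with
#' drift parameter `fst = 0.1` per population. Haplotypes are founder
#' mosaics (`founder_k` founders per population, per-bp switch probability
#' `switch_rate`) which gives tunable local LD; an optional sweep collapses
#' the focal founder pool to `sweep$founders` haplotype(s) inside the sweep
#' interval and injects singleton post-sweep mutations at `sweep$rare_per_bp`
#' per bp (a rate proportional to the mutation parameter `theta`).
#'
#' @param pops Named integer vector: population label -> diploid count.
#' @param fst Balding-Nichols drift parameter, one value or one per
#'   population, each in (0, 1).
#' @param n_sites Number of SNP sites.
#' @param contig_length Contig length in bp.
#' @param contig Contig name.
#' @param founder_k Founder haplotypes per population.
#' @param switch_rate Per-bp founder-switch (mosaic recombination proxy)
#'   probability.
#' @param theta Coalescent mutation parameter (used by
#'   [simulate_coalescent()] calibrations).
#' @param sweep `NULL`, or a list with `pop`, `center` (bp), `width` (bp),
#'   `founders` (collapsed founder pool size) and `rare_per_bp`.
#' @param seed Integer seed fixing all randomness.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(pops = c(Yanbian = 8L, Hanwoo = 17L,
                                Holstein = 10L, Angus = 10L),
                       fst = 0.1, n_sites = 30000L, contig_length = 2e7,
                       contig = "1", founder_k = 8L, switch_rate = 1e-5,
                       theta = 5,
                       sweep = list(pop = "Yanbian", center = 1e7,
                                    width = 2e5, founders = 1L,
                                    rare_per_bp = 2e-4),
                       seed = 1L) {
  if (is.null(names(pops))) stop("pops must be named by population")
  if (any(pops < 2)) stop("each population needs >= 2 diploids")
  if (length(fst) == 1L) fst <- setNames(rep(fst, length(pops)), names(pops))
  if (any(fst <= 0 | fst >= 1)) stop("fst must lie strictly in (0, 1)")
  if (!is.null(sweep) && !sweep$pop %in% names(pops))
    stop("sweep population '", sweep$pop, "' not in pops")
  structure(list(pops = pops, fst = fst, n_sites = as.integer(n_sites),
                 contig_length = contig_length, contig = contig,
                 founder_k = as.integer(founder_k),
                 switch_rate = switch_rate, theta = theta, sweep = sweep,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# shared site scaffold: positions, ancestral and per-pop frequencies
bn_frequencies <- function(cfg) {
  m <- cfg$n_sites
  pos <- sort(sample.int(cfg$contig_length, m))
  anc <- runif(m, 0.05, 0.95)
  pf <- vapply(names(cfg$pops), function(p) {
    F <- cfg$fst[[p]]
    rbeta(m, anc * (1 - F) / F, (1 - anc) * (1 - F) / F)
  }, numeric(m))
  list(pos = pos, anc = anc, pop_freq = pf)
}

#' Simulate Balding-Nichols genotypes
#'
#' Ancestral allele frequencies are Uniform(0.05, 0.95) per site; each
#' population's frequency is Beta-distributed around the ancestral value
#' with drift parameter `F` (`Beta(p(1-F)/F, (1-p)(1-F)/F)`), and diploid
#' dosages are Binomial(2, population frequency). Site positions are
#' uniform over the contig. The generating frequencies are attached as the
#' `truth` attribute.
#'
#' @param cfg A [sim_config()].
#' @return A [genotype_matrix()] with attribute `truth` (list: `anc`,
#'   `pop_freq`).
#' @export
simulate_bn_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  sc <- bn_frequencies(cfg)
  m <- cfg$n_sites
  dos <- do.call(rbind, lapply(names(cfg$pops), function(p) {
    n <- cfg$pops[[p]]
    matrix(rbinom(n * m, 2, rep(sc$pop_freq[, p], each = n)), nrow = n)
  }))
  pop <- rep(names(cfg$pops), cfg$pops)
  rownames(dos) <- paste0(pop, "_", unlist(lapply(cfg$pops, seq_len)))
  gm <- genotype_matrix(rep(cfg$contig, m), sc$pos,
                        rep("A", m), rep("C", m), dos,
                        setNames(pop, rownames(dos)))
  attr(gm, "truth") <- list(anc = sc$anc, pop_freq = sc$pop_freq)
  gm
}

#' Simulate phased haplotypes with local LD and an optional planted sweep
#'
#' Per population, `founder_k` founder haplotypes are drawn from the
#' population's Balding-Nichols frequencies; each sampled haplotype is a
#' mosaic of founders with per-bp switch probability `switch_rate`. Inside
#' the sweep interval of the focal population the founder pool collapses to
#' `sweep$founders` haplotype(s) (a hard sweep leaves essentially one core
#' haplotype) and singleton post-sweep mutations are injected at
#' `sweep$rare_per_bp` per bp, reproducing the sweep signature: extended
#' haplotype homozygosity, reduced diversity, excess rare variants.
#'
#' @param cfg A [sim_config()] (with or without `sweep`).
#' @return A [haplotype_matrix()] with attribute `truth` (list: `pop_freq`,
#'   `sweep` interval and collapsed-founder assignment, `rare_pos`).
#' @export
simulate_sweep_haplotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  sc <- bn_frequencies(cfg)
  m <- cfg$n_sites
  pos <- sc$pos
  gaps <- c(0, diff(pos))
  p_switch <- 1 - exp(-cfg$switch_rate * gaps)
  hap_list <- list()
  founders_by_pop <- list()
  for (p in names(cfg$pops)) {
    n_hap <- 2L * cfg$pops[[p]]
    founders <- matrix(rbinom(cfg$founder_k * m, 1, rep(sc$pop_freq[, p],
                                                        each = cfg$founder_k)),
                       nrow = cfg$founder_k)
    founders_by_pop[[p]] <- founders
    hap <- matrix(0L, n_hap, m)
    for (i in seq_len(n_hap)) {
      seg <- 1L + cumsum(runif(m) < p_switch)
      fid <- sample.int(cfg$founder_k, max(seg), replace = TRUE)
      hap[i, ] <- founders[cbind(fid[seg], seq_len(m))]
    }
    hap_list[[p]] <- hap
  }
  truth <- list(pop_freq = sc$pop_freq, sweep = NULL, rare_pos = integer())
  ref <- rep("A", m); alt <- rep("C", m)
  if (!is.null(cfg$sweep)) {
    sw <- cfg$sweep
    lo <- sw$center - sw$width / 2
    hi <- sw$center + sw$width / 2
    in_sweep <- which(pos >= lo & pos <= hi)
    focal <- hap_list[[sw$pop]]
    pool <- founders_by_pop[[sw$pop]][
      sample.int(cfg$founder_k, sw$founders), in_sweep, drop = FALSE]
    founder_of <- sample.int(sw$founders, nrow(focal), replace = TRUE)
    focal[, in_sweep] <- pool[founder_of, , drop = FALSE]
    hap_list[[sw$pop]] <- focal
    # singleton post-sweep mutations on new sites inside the sweep
    n_rare <- rpois(1, sw$rare_per_bp * sw$width)
    rare_pos <- sort(unique(round(runif(n_rare, lo, hi))))
    rare_pos <- setdiff(rare_pos, pos)
    if (length(rare_pos) > 0) {
      carrier <- sample.int(nrow(focal), length(rare_pos), replace = TRUE)
      add <- lapply(names(cfg$pops), function(p) {
        blk <- matrix(0L, nrow(hap_list[[p]]), length(rare_pos))
        if (p == sw$pop) blk[cbind(carrier, seq_along(rare_pos))] <- 1L
        blk
      })
      names(add) <- names(cfg$pops)
      ord <- order(c(pos, rare_pos))
      for (p in names(cfg$pops))
        hap_list[[p]] <- cbind(hap_list[[p]], add[[p]])[, ord, drop = FALSE]
      ref <- rep("A", m + length(rare_pos))
      alt <- rep("C", m + length(rare_pos))
      pos <- c(pos, rare_pos)[ord]
    }
    truth$sweep <- list(pop = sw$pop, lo = lo, hi = hi,
                        center = sw$center, founders = sw$founders,
                        assignment = founder_of)
    truth$rare_pos <- rare_pos
  }
  allele <- do.call(rbind, hap_list)
  pop <- rep(names(cfg$pops), cfg$pops)
  samples <- paste0(pop, "_", unlist(lapply(cfg$pops, seq_len)))
  hm <- haplotype_matrix(rep(cfg$contig, length(pos)), pos, ref, alt,
                         allele, setNames(pop, samples), samples = samples)
  attr(hm, "truth") <- truth
  hm
}

#' Neutral coalescent simulator (single locus, infinite sites)
#'
#' Standard constant-size coalescent for `n` haploid sequences at one
#' non-recombining locus. While `k` lineages are active the waiting time is
#' Exponential(k(k-1)/2) (units of 2N generations); mutations fall as a
#' Poisson process with rate `theta / 2` per lineage per unit time and are
#' placed uniformly, each creating one bi-allelic site (infinite-sites).
#'
#' @param n Number of haploid sequences (>= 2).
#' @param theta Population-scaled mutation parameter (4 N mu for the locus).
#' @param replicates Number of independent replicates.
#' @param seed Integer seed.
#' @return List of replicates; each is a list with `hap` (n x S 0/1
#'   matrix), `pos` (sorted Uniform(0,1) relative site positions),
#'   `S`, `tmrca`, `total_branch`.
#' @export
simulate_coalescent <- function(n, theta, replicates = 1L, seed = 1L) {
  if (n < 2) stop("need at least 2 sequences")
  set.seed(seed)
  lapply(seq_len(replicates), function(r) {
    lineages <- as.list(seq_len(n))
    tmrca <- 0; ttot <- 0
    derived <- list()
    k <- n
    while (k > 1L) {
      tk <- rexp(1, rate = k * (k - 1) / 2)
      tmrca <- tmrca + tk
      ttot <- ttot + k * tk
      n_mut <- rpois(1, theta / 2 * k * tk)
      if (n_mut > 0) {
        on_lineage <- sample.int(k, n_mut, replace = TRUE)
        for (mu in on_lineage)
          derived[[length(derived) + 1L]] <- lineages[[mu]]
      }
      pair <- sample.int(k, 2)
      merged <- c(lineages[[pair[1]]], lineages[[pair[2]]])
      lineages <- c(lineages[-pair], list(merged))
      k <- k - 1L
    }
    S <- length(derived)
    hap <- matrix(0L, n, S)
    for (j in seq_len(S)) hap[derived[[j]], j] <- 1L
    # mutations are exchangeable, so sorted uniform positions can be
    # assigned to columns directly
    pos <- sort(runif(S))
    list(hap = hap, pos = pos, S = S, tmrca = tmrca, total_branch = ttot)
  })
}

#' Convert one coalescent replicate to diploid genotypes in a window
#'
#' Pairs consecutive haplotypes into diploids (requires even `n`) and
#' scatters the relative site positions across `start..start+length-1`,
#' for calibrating the windowed diversity statistics.
#'
#' @param x One replicate from [simulate_coalescent()].
#' @param chrom Contig name.
#' @param start Window start (1-based).
#' @param win_len Window length in bp.
#' @param pop Population label to assign.
#' @return A [genotype_matrix()] (zero-site replicates return `NULL`).
#' @export
coalescent_to_genotypes <- function(x, chrom = "1", start = 1L,
                                    win_len = 1e4, pop = "POP") {
  n <- nrow(x$hap)
  if (n %% 2L != 0L) stop("need an even number of haplotypes to pair")
  if (x$S == 0L) return(NULL)
  pos <- start + floor(x$pos * (win_len - 1))
  keep <- !duplicated(pos)
  pos <- pos[keep]
  hap <- x$hap[, keep, drop = FALSE]
  dos <- hap[seq(1, n, 2), , drop = FALSE] + hap[seq(2, n, 2), , drop = FALSE]
  genotype_matrix(rep(chrom, ncol(hap)), pos,
                  rep("A", ncol(hap)), rep("C", ncol(hap)), dos,
                  setNames(rep(pop, n / 2), paste0("S", seq_len(n / 2))))
}
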