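#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test conditioning on the observed allele counts: the
#' p-value is the total probability, under random union of gametes, of all
#' heterozygote counts whose conditional probability does not exceed that of
#' the observed count. Computed with the standard recurrence over possible
#' heterozygote counts (no mid-p adjustment).
#'
#' @param n_hom_ref,n_het,n_hom_alt Genotype counts (non-negative, total >= 1).
#' @return The exact two-sided p-value.
#' @export
hwe_exact_p <- function(n_hom_ref, n_het, n_hom_alt) {
  if (any(c(n_hom_ref, n_het, n_hom_alt) < 0))
    stop("genotype counts must be non-negative")
  n <- n_hom_ref + n_het + n_hom_alt
  if (n < 1) stop("at least one genotype is required")
  n_a <- 2L * n_hom_alt + n_het      # minor-ish allele count (alt)
  n_r <- 2L * n_hom_ref + n_het
  rare <- min(n_a, n_r)              # rarer allele count
  if (rare == 0L) return(1.0)        # monomorphic: single outcome
  # possible het counts share the parity of the rarer allele count
  hets <- seq(rare %% 2L, rare, by = 2L)
  # unnormalized probabilities via the recurrence
  # P(h+2)/P(h) = 4 * n_AA(h) * n_aa(h) / ((h+2)*(h+1))
  lp <- numeric(length(hets))
  for (k in seq_along(hets)[-1]) {
    h <- hets[k - 1]
    hom_rare <- (rare - h) / 2
    hom_comm <- n - h - hom_rare
    lp[k] <- lp[k - 1] + log(4) + log(hom_rare) + log(hom_comm) -
      log(h + 2) - log(h + 1)
  }
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  obs <- match(n_het, hets)
  if (is.na(obs)) stop("heterozygote count inconsistent with allele counts")
  min(1, sum(p[p <= p[obs] * (1 + 1e-12)]))
}

#' Site quality-control thresholds
#'
#' Defaults mirror common whole-genome SNP filtering: HWE exact p >= 1e-6,
#' minor allele frequency >= 0.05, and a (permissive) minimum call rate of
#' 0.05 in the VCFtools `--max-missing` convention, where the value is the
#' minimum *proportion of called genotypes* required.
#'
#' @param hwe_p_min,maf_min,callrate_min Probabilities in `[0, 1]`.
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(hwe_p_min = 1e-6, maf_min = 0.05,
                          callrate_min = 0.05) {
  vals <- c(hwe_p_min, maf_min, callrate_min)
  if (any(vals < 0 | vals > 1)) stop("thresholds must lie in [0, 1]")
  structure(list(hwe_p_min = hwe_p_min, maf_min = maf_min,
                 callrate_min = callrate_min), class = "qc_thresholds")
}

#' Filter SNP sites on HWE, MAF and call rate
#'
#' Criteria are applied in the order HWE (all samples pooled), MAF (on
#' non-missing alleles), call rate; the report counts removals per criterion
#' in that order, so a site failing several is charged to the first.
#'
#' @param gm A [genotype_matrix()].
#' @param thr A [qc_thresholds()].
#' @return A list: `gm` (filtered [genotype_matrix()]) and `report`
#'   (data.frame with columns `criterion`, `removed`, `retained`).
#' @export
filter_sites <- function(gm, thr = qc_thresholds()) {
  stopifnot(inherits(gm, "genotype_matrix"))
  d <- gm$dosage
  n_samp <- nrow(d)
  called <- colSums(!is.na(d))
  alt <- colSums(d, na.rm = TRUE)
  af <- ifelse(called > 0, alt / (2 * called), NA)
  maf <- pmin(af, 1 - af)
  n_het <- colSums(d == 1, na.rm = TRUE)
  n_hom_alt <- colSums(d == 2, na.rm = TRUE)
  n_hom_ref <- called - n_het - n_hom_alt
  hwe_p <- vapply(seq_len(ncol(d)), function(j) {
    if (called[j] == 0) return(NA_real_)
    hwe_exact_p(n_hom_ref[j], n_het[j], n_hom_alt[j])
  }, numeric(1))

  fail_hwe <- !is.na(hwe_p) & hwe_p < thr$hwe_p_min
  fail_maf <- !fail_hwe & (is.na(maf) | maf < thr$maf_min)
  fail_cr <- !fail_hwe & !fail_maf & (called / n_samp < thr$callrate_min)
  keep <- !(fail_hwe | fail_maf | fail_cr)
  report <- data.frame(
    criterion = c("hwe", "maf", "callrate"),
    removed = c(sum(fail_hwe), sum(fail_maf), sum(fail_cr)),
    retained = sum(keep))
  list(gm = subset_sites(gm, which(keep)), report = report)
}

#' LD-pruning parameters (`--indep-pairwise` convention)
#'
#' @param window_snps,step_snps SNP-count window and step (defaults 50 / 10).
#' @param r2_max Maximum allowed pairwise dosage r-squared (default 0.1).
#' @return A list of class `prune_params`.
#' @export
prune_params <- function(window_snps = 50L, step_snps = 10L, r2_max = 0.1) {
  if (step_snps > window_snps) stop("step_snps must not exceed window_snps")
  if (r2_max < 0 || r2_max > 1) stop("r2_max must lie in [0, 1]")
  structure(list(window_snps = as.integer(window_snps),
                 step_snps = as.integer(step_snps), r2_max = r2_max),
            class = "prune_params")
}

#' Greedy sliding-window LD pruning on genotype dosages
#'
#' Within each `window_snps`-SNP window, while any retained pair has
#' composite (dosage) correlation r-squared above `r2_max`, the later site of
#' the offending pair is dropped; the window then advances by `step_snps`
#' SNPs. Deterministic given the input order. Monomorphic sites never trigger
#' removals.
#'
#' @param gm A [genotype_matrix()] with sites ordered by position.
#' @param pp A [prune_params()].
#' @return Integer vector of retained site indices.
#' @export
ld_prune <- function(gm, pp = prune_params()) {
  stopifnot(inherits(gm, "genotype_matrix"))
  d <- gm$dosage
  m <- ncol(d)
  keep <- rep(TRUE, m)
  if (m < 2L) return(which(keep))
  start <- 1L
  repeat {
    end <- min(start + pp$window_snps - 1L, m)
    idx <- which(keep[start:end]) + start - 1L
    poly <- idx[apply(d[, idx, drop = FALSE], 2,
                      function(x) length(unique(x[!is.na(x)])) > 1L)]
    if (length(poly) >= 2L) {
      repeat {
        r2 <- suppressWarnings(
          cor(d[, poly, drop = FALSE], use = "pairwise.complete.obs"))^2
        r2[!is.finite(r2)] <- 0
        diag(r2) <- 0
        offending <- which(r2 > pp$r2_max, arr.ind = TRUE)
        if (nrow(offending) == 0L) break
        # later site of the first offending pair (lowest indices first)
        pair <- offending[order(pmin(offending[, 1], offending[, 2]),
                                pmax(offending[, 1], offending[, 2]))[1], ]
        drop_site <- poly[max(pair)]
        keep[drop_site] <- FALSE
        poly <- poly[poly != drop_site]
        if (length(poly) < 2L) break
      }
    }
    if (end >= m) break
    start <- start + pp$step_snps
  }
  which(keep)
}

#' Count breed-specific SNPs by exact test against all other populations
#'
#' At every site and for every population, alternate/reference allele counts
#' in that population are tested against the pooled counts of all other
#' populations with Fisher's exact test. A site is *breed-specific* for the
#' population with the smallest p-value when that p-value is below
#' `alpha / n_sites` (Bonferroni over sites tested).
#'
#' @param gm A [genotype_matrix()] with at least two populations.
#' @param alpha Family-wise significance level (default 0.05).
#' @return Named integer vector: breed-specific SNP count per population.
#' @export
breed_specific_counts <- function(gm, alpha = 0.05) {
  stopifnot(inherits(gm, "genotype_matrix"))
  pops <- sort(unique(gm$pop))
  if (length(pops) < 2L) stop("at least two populations are required")
  if (any(table(gm$pop) == 0)) stop("population with zero samples")
  m <- ncol(gm$dosage)
  alt_by_pop <- vapply(pops, function(p)
    colSums(gm$dosage[sample_rows(gm, p), , drop = FALSE], na.rm = TRUE),
    numeric(m))
  called_by_pop <- vapply(pops, function(p)
    2 * colSums(!is.na(gm$dosage[sample_rows(gm, p), , drop = FALSE])),
    numeric(m))
  if (m == 1L) {
    alt_by_pop <- matrix(alt_by_pop, nrow = 1, dimnames = list(NULL, pops))
    called_by_pop <- matrix(called_by_pop, nrow = 1,
                            dimnames = list(NULL, pops))
  }
  counts <- setNames(integer(length(pops)), pops)
  thr <- alpha / m
  for (j in seq_len(m)) {
    pvals <- vapply(pops, function(p) {
      a <- alt_by_pop[j, p]; n1 <- called_by_pop[j, p]
      b <- sum(alt_by_pop[j, ]) - a
      n2 <- sum(called_by_pop[j, ]) - n1
      tab <- matrix(c(a, n1 - a, b, n2 - b), nrow = 2)
      if (any(tab < 0) || n1 == 0 || n2 == 0) return(1)
      fisher.test(round(tab))$p.value
    }, numeric(1))
    best <- which.min(pvals)
    if (pvals[best] < thr)
      counts[best] <- counts[best] + 1L
  }
  counts
}
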