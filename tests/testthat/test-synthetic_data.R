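test_that("generators are fully deterministic under a fixed seed", {
  cfg <- sim_config(pops = c(A = 4L, B = 4L), n_sites = 300L,
                    contig_length = 1e6,
                    sweep = list(pop = "A", center = 5e5, width = 1e5,
                                 founders = 1L, rare_per_bp = 2e-4),
                    seed = 91)
  expect_identical(simulate_bn_genotypes(cfg), simulate_bn_genotypes(cfg))
  expect_identical(simulate_sweep_haplotypes(cfg),
                   simulate_sweep_haplotypes(cfg))
  expect_identical(simulate_coalescent(10, 3, 5, seed = 91),
                   simulate_coalescent(10, 3, 5, seed = 91))
})

test_that("Balding-Nichols differentiation scales with the drift parameter", {
  # near-zero drift: window F_ST < 0.01
  cfg0 <- sim_config(pops = c(A = 30L, B = 30L), fst = 0.001,
                     n_sites = 3000L, contig_length = 49999, sweep = NULL,
                     seed = 92)
  gm0 <- simulate_bn_genotypes(cfg0)
  w <- make_windows(c("1" = 49999), 50000, 50000)
  f0 <- wc_fst_window(wc_fst_site(gm0, "A", "B"), w)
  expect_lt(abs(f0$value), 0.01)

  # F = 0.1 recovered within 0.02 against the direct frequency-based oracle
  cfg1 <- sim_config(pops = c(A = 30L, B = 30L), fst = 0.1, n_sites = 2000L,
                     contig_length = 49999, sweep = NULL, seed = 93)
  gm1 <- simulate_bn_genotypes(cfg1)
  f1 <- wc_fst_window(wc_fst_site(gm1, "A", "B"), w)
  expect_lt(abs(f1$value - 0.1), 0.02)
  # truth record carries the generating frequencies
  tr <- attr(gm1, "truth")
  expect_equal(dim(tr$pop_freq), c(2000L, 2L))
  expect_true(all(tr$anc >= 0.05 & tr$anc <= 0.95))
})

test_that("planted sweeps collapse haplotypes and leave rare variants", {
  cfg <- sim_config(seed = 94, n_sites = 5000L, contig_length = 4e6,
                    sweep = list(pop = "Yanbian", center = 2e6, width = 2e5,
                                 founders = 1L, rare_per_bp = 2e-4))
  hm <- simulate_sweep_haplotypes(cfg)
  tr <- attr(hm, "truth")
  foc <- hm$allele[hm$hap_pop == "Yanbian", ]
  insw <- hm$pos >= tr$sweep$lo & hm$pos <= tr$sweep$hi
  core_sites <- insw & !(hm$pos %in% tr$rare_pos)
  # single founder: all focal haplotypes identical at non-rare sweep sites
  expect_true(all(apply(foc[, core_sites], 2,
                        function(x) length(unique(x)) == 1L)))
  # rare variants are singletons confined to the focal population
  rare_cols <- which(hm$pos %in% tr$rare_pos)
  expect_true(all(colSums(hm$allele[, rare_cols, drop = FALSE]) == 1))
  expect_true(all(colSums(foc[, rare_cols, drop = FALSE]) == 1))
  # collapse to one founder with no new mutations: EHH = 1 across the sweep
  cfg1 <- cfg
  cfg1$sweep$rare_per_bp <- 0
  hm1 <- simulate_sweep_haplotypes(cfg1)
  tr1 <- attr(hm1, "truth")
  core1 <- which.min(abs(hm1$pos - 2e6))
  prof <- ehh(hm1, "Yanbian", core1)
  half <- min(2e6 - tr1$sweep$lo, tr1$sweep$hi - 2e6)
  expect_true(all(prof$ehh_left[prof$dist_left <= half] == 1))
  expect_true(all(prof$ehh_right[prof$dist_right <= half] == 1))

  # focal diversity collapses inside the sweep, D goes negative
  gm <- as_genotype_matrix(hm)
  w <- make_windows(c("1" = 4e6), 5e4, 5e4)
  pit <- window_pi(gm, "Yanbian", w)
  sw <- pit$start >= tr$sweep$lo & pit$end <= tr$sweep$hi
  expect_lt(mean(pit$value[sw]), 0.25 * mean(pit$value[!sw]))
  td <- tajimas_d(gm, "Yanbian", w)
  expect_lt(mean(td$value[sw], na.rm = TRUE), 0)
})

test_that("without a sweep the focal population is exchangeable", {
  cfg <- sim_config(pops = c(A = 10L, B = 10L), n_sites = 12000L,
                    contig_length = 8e6, sweep = NULL, seed = 95)
  hm <- simulate_sweep_haplotypes(cfg)
  scan <- xpehh_scan(hm, "A", "B")
  wm <- window_max(scan$chrom, scan$pos, scan$normalized,
                   make_windows(c("1" = 8e6), 5e4, 5e4))
  rev_scan <- xpehh_scan(hm, "B", "A")
  wm_rev <- window_max(rev_scan$chrom, rev_scan$pos, rev_scan$normalized,
                       make_windows(c("1" = 8e6), 5e4, 5e4))
  # two-sample location test on the window maxima: no detectable shift
  p <- wilcox.test(wm$value, wm_rev$value)$p.value
  expect_gt(p, 0.01)
})

test_that("coalescent matches Watterson, Tajima and TMRCA expectations", {
  n <- 20; theta <- 5; R <- 1500
  reps <- simulate_coalescent(n, theta, replicates = R, seed = 96)
  S <- vapply(reps, `[[`, numeric(1), "S")
  a1 <- sum(1 / seq_len(n - 1))
  se_S <- sd(S) / sqrt(R)
  expect_lt(abs(mean(S) - theta * a1), 3 * se_S)
  # mean pairwise diversity estimates theta
  pis <- vapply(reps, function(r) {
    if (r$S == 0) return(0)
    dac <- colSums(r$hap)
    sum(2 * dac * (n - dac) / (n * (n - 1)))
  }, numeric(1))
  expect_lt(abs(mean(pis) - theta), 3 * sd(pis) / sqrt(R))
  # n = 2: TMRCA is Exponential(1) in units of 2N generations
  reps2 <- simulate_coalescent(2, 1, replicates = 2000, seed = 97)
  tm <- vapply(reps2, `[[`, numeric(1), "tmrca")
  expect_lt(abs(mean(tm) - 1), 3 * sd(tm) / sqrt(2000))
})
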