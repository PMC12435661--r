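test_that("per-site pi follows the unbiased pairwise formula", {
  # 1 site, 2 samples (4 alleles), allele counts 2/2, 1 kb window
  gm <- genotype_matrix("1", 500L, "A", "C", matrix(c(1, 1), ncol = 1),
                        pop = c("P", "P"))
  w <- make_windows(c("1" = 1000), 1000, 1000)
  pit <- window_pi(gm, "P", w)
  expect_equal(pit$value, (2 * 2 * 2) / (4 * 3) / 1000)

  # monomorphic window -> 0
  gm0 <- genotype_matrix("1", 500L, "A", "C", matrix(c(0, 0), ncol = 1),
                         pop = c("P", "P"))
  expect_equal(window_pi(gm0, "P", w)$value, 0)

  # pi is invariant under swapping ref/alt labels
  set.seed(41)
  dos <- vapply(1:50, function(j) rbinom(10, 2, runif(1, .1, .9)),
                numeric(10))
  gm1 <- genotype_matrix(rep("1", 50), sort(sample.int(1e4, 50)),
                         rep("A", 50), rep("C", 50), dos, rep("P", 10))
  gm2 <- gm1; gm2$dosage <- 2 - gm1$dosage
  w2 <- make_windows(c("1" = 1e4), 1e4, 1e4)
  expect_equal(window_pi(gm1, "P", w2)$value, window_pi(gm2, "P", w2)$value)
  expect_gte(min(window_pi(gm1, "P", w2)$value), 0)
})

test_that("Tajima's D matches the direct-constants oracle", {
  set.seed(42)
  for (rep_i in 1:20) {
    n_hap <- 2 * sample(2:15, 1)
    S <- sample(3:40, 1)
    hap <- matrix(0L, n_hap, S)
    for (j in seq_len(S))
      hap[sample.int(n_hap, sample.int(n_hap - 1, 1)), j] <- 1L
    dos <- hap[seq(1, n_hap, 2), , drop = FALSE] +
      hap[seq(2, n_hap, 2), , drop = FALSE]
    gm <- genotype_matrix(rep("1", S), sort(sample.int(1e4, S)),
                          rep("A", S), rep("C", S), dos,
                          rep("P", n_hap / 2))
    w <- make_windows(c("1" = 1e4), 1e4, 1e4)
    expect_equal(tajimas_d(gm, "P", w, min_snps = 1)$value,
                 oracle_tajimas_d(hap), tolerance = 1e-10)
  }
})

test_that("windows with too few segregating sites are undefined, not zero", {
  gm <- genotype_matrix(rep("1", 2), c(100L, 200L), rep("A", 2), rep("C", 2),
                        matrix(0, nrow = 4, ncol = 2), pop = rep("P", 4))
  w <- make_windows(c("1" = 1000), 1000, 1000)
  expect_true(is.na(tajimas_d(gm, "P", w)$value))     # S = 0
  expect_error(tajimas_d(
    genotype_matrix("1", 100L, "A", "C", matrix(1, 1, 1), pop = "P"),
    "P", w), "at least 4")
})

test_that("Tajima's D sign tracks the frequency spectrum", {
  n_hap <- 20; S <- 30
  # only singletons -> negative D
  sing <- matrix(0L, n_hap, S)
  for (j in seq_len(S)) sing[sample.int(n_hap, 1), j] <- 1L
  # only intermediate-frequency variants -> positive D
  mid <- matrix(0L, n_hap, S)
  for (j in seq_len(S)) mid[sample.int(n_hap, n_hap / 2), j] <- 1L
  expect_lt(oracle_tajimas_d(sing), 0)
  expect_gt(oracle_tajimas_d(mid), 0)
  to_gm <- function(hap) {
    dos <- hap[seq(1, n_hap, 2), ] + hap[seq(2, n_hap, 2), ]
    genotype_matrix(rep("1", S), sort(sample.int(1e4, S)), rep("A", S),
                    rep("C", S), dos, rep("P", n_hap / 2))
  }
  w <- make_windows(c("1" = 1e4), 1e4, 1e4)
  expect_lt(tajimas_d(to_gm(sing), "P", w)$value, 0)
  expect_gt(tajimas_d(to_gm(mid), "P", w)$value, 0)
})

test_that("gene-size rule selects the documented window parameters", {
  # a 144,506 bp gene: 50/25 kb pi windows, 10 kb D windows
  big <- diversity_params(144506)
  expect_equal(big$tajd_size, 10000L)
  expect_equal(c(big$pi_size, big$pi_step), c(50000L, 25000L))
  # a 12,522 bp gene: 1 kb / 0.5 kb pi windows, 5 kb D windows
  small <- diversity_params(12522)
  expect_equal(small$tajd_size, 5000L)
  expect_equal(c(small$pi_size, small$pi_step), c(1000L, 500L))
})

test_that("gene_region_scan spans gene +/- flank and flags sparse windows", {
  cfg <- sim_config(pops = c(P = 10L, Q = 10L), n_sites = 2000L,
                    contig_length = 5e5, sweep = NULL, seed = 43)
  gm <- simulate_bn_genotypes(cfg)
  gene <- data.frame(gene_id = "g", gene_name = "g", chrom = "1",
                     start = 200001L, end = 212522L, strand = "+")
  sc <- gene_region_scan(gm, "P", gene, flank = 0)
  expect_equal(min(sc$pi$start), 200001L)
  expect_lte(max(sc$pi$end), 212522L)
  expect_equal(sc$params$tajd_size, 5000L)
  sc2 <- gene_region_scan(gm, "P", gene)  # default flank = one pi window
  expect_equal(min(sc2$pi$start), 200001L - 1000L)
  bad_gene <- gene; bad_gene$chrom <- "chrUn"
  expect_error(gene_region_scan(gm, "P", bad_gene), "absent")
})

test_that("neutral coalescent windows calibrate pi and Tajima's D", {
  theta <- 4; L <- 1e4; n_rep <- 400
  reps <- simulate_coalescent(20, theta, replicates = n_rep, seed = 44)
  w <- make_windows(c("1" = L), L, L)
  pis <- ds <- rep(NA_real_, n_rep)
  for (i in seq_along(reps)) {
    gm <- coalescent_to_genotypes(reps[[i]], win_len = L)
    if (is.null(gm)) { pis[i] <- 0; next }
    pis[i] <- window_pi(gm, "POP", w)$value * L
    d <- tajimas_d(gm, "POP", w, min_snps = 3)$value
    ds[i] <- d
  }
  se_pi <- sd(pis) / sqrt(n_rep)
  expect_lt(abs(mean(pis) - theta), 3 * se_pi)
  expect_lt(abs(mean(ds, na.rm = TRUE)), 0.2)
})
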