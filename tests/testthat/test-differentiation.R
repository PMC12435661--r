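test_that("per-site WC components match fixation and identity contracts", {
  gm <- genotype_matrix("1", 100L, "A", "C",
                        matrix(c(rep(0, 5), rep(2, 5)), ncol = 1),
                        pop = rep(c("A", "B"), each = 5))
  comp <- wc_fst_site(gm, "A", "B")
  expect_equal(comp$theta, 1)

  # identical genotype vectors -> a <= 0, theta <= 0
  set.seed(51)
  g <- rbinom(5, 2, 0.5)
  gm2 <- genotype_matrix("1", 100L, "A", "C", matrix(c(g, g), ncol = 1),
                         pop = rep(c("A", "B"), each = 5))
  comp2 <- wc_fst_site(gm2, "A", "B")
  expect_lte(comp2$a, 0)
  expect_lte(comp2$theta, 0)

  # symmetry in population order
  gm3 <- genotype_matrix("1", 100L, "A", "C",
                         matrix(c(0, 0, 1, 1, 2, 0, 1, 1, 2, 2), ncol = 1),
                         pop = rep(c("A", "B"), each = 5))
  expect_equal(wc_fst_site(gm3, "A", "B")$theta,
               wc_fst_site(gm3, "B", "A")$theta)
})

test_that("WC components equal an independent transcription on random tables", {
  set.seed(52)
  for (i in 1:300) {
    nA <- sample(2:12, 1); nB <- sample(2:12, 1)
    gA <- rbinom(nA, 2, runif(1, 0.05, 0.95))
    gB <- rbinom(nB, 2, runif(1, 0.05, 0.95))
    gm <- genotype_matrix("1", 100L, "A", "C", matrix(c(gA, gB), ncol = 1),
                          pop = rep(c("A", "B"), c(nA, nB)))
    comp <- wc_fst_site(gm, "A", "B")
    oc <- oracle_wc_components(gA, gB)
    expect_equal(c(comp$a, comp$b, comp$c), unname(oc), tolerance = 1e-12)
  }
})

test_that("windowed ratio-of-sums F_ST recovers the drift parameter", {
  cfg <- sim_config(pops = c(A = 25L, B = 25L), fst = 0.1, n_sites = 2000L,
                    contig_length = 49999, sweep = NULL, seed = 53)
  gm <- simulate_bn_genotypes(cfg)
  comp <- wc_fst_site(gm, "A", "B")
  w <- make_windows(c("1" = 49999), 50000, 50000)
  fw <- wc_fst_window(comp, w)
  expect_equal(fw$n_sites, 2000L)
  expect_lt(abs(fw$value - 0.1), 0.02)

  # all sites fixed-different -> window F_ST = 1; empty window -> NA
  gmf <- genotype_matrix(rep("1", 3), c(10L, 20L, 30L), rep("A", 3),
                         rep("C", 3),
                         matrix(rep(c(0, 2), c(5, 5)), nrow = 10, ncol = 3),
                         pop = rep(c("A", "B"), each = 5))
  fwf <- wc_fst_window(wc_fst_site(gmf, "A", "B"),
                       make_windows(c("1" = 2000), 1000, 1000))
  expect_equal(fwf$value[1], 1)
  expect_true(is.na(fwf$value[2]))
})

test_that("branch lengths transform F_ST as -ln(1 - fst)", {
  expect_equal(branch_length(0), 0)
  expect_equal(branch_length(0.5), log(2))
  expect_equal(branch_length(0.1), -log(0.9))
  # strictly increasing on [0, 1)
  x <- seq(0, 0.99, by = 0.01)
  expect_true(all(diff(branch_length(x)) > 0))
  expect_error(branch_length(1), "infinite")
  expect_error(branch_length(-0.05), "exclude")
})

test_that("PBS4 algebra and undefined-window flagging", {
  grid <- make_windows(c("1" = 1e5), 5e4, 5e4)
  mk <- function(v) { g <- grid; g$value <- v; g }
  pops <- c("YB", "Han", "Hol", "Ang")
  cfg <- pbs4_config("YB", "Han", c("Hol", "Ang"))
  keys <- c("Han|YB", "Hol|YB", "Ang|YB", "Han|Hol", "Ang|Han", "Ang|Hol")
  # all five branch lengths equal d -> PBS4 = d / 2
  d <- 0.2; fst_d <- 1 - exp(-d)
  tracks <- setNames(lapply(keys, function(k) mk(c(fst_d, fst_d))), keys)
  pb <- pbs4(tracks, cfg)
  expect_equal(pb$value, c(d / 2, d / 2))

  # zero focal branches with drifted sister-outgroup branches -> negative
  dz <- 1 - exp(-0.2)
  vals <- list("Han|YB" = 0, "Hol|YB" = 0, "Ang|YB" = 0,
               "Han|Hol" = dz, "Ang|Han" = dz, "Ang|Hol" = 0.1)
  tracks2 <- setNames(lapply(keys, function(k) mk(rep(vals[[k]], 2))), keys)
  pb2 <- pbs4(tracks2, cfg, exclude = "pair")
  expect_equal(pb2$value, rep(-0.1, 2))

  # F_ST = 0 in a required pair is excluded in whole-window mode
  pb2w <- pbs4(tracks2, cfg)
  expect_true(all(is.na(pb2w$value)))

  # missing pair value -> window undefined, not zero
  tracks3 <- tracks
  tracks3[["Han|YB"]]$value[2] <- NA
  pb3 <- pbs4(tracks3, cfg)
  expect_false(is.na(pb3$value[1]))
  expect_true(is.na(pb3$value[2]))

  expect_error(pbs4(tracks[-1], cfg), "missing pairwise")
  expect_error(pbs4_config("A", "A", c("B", "C")), "distinct")
})

test_that("pipeline PBS4 equals naive recomputation on every window", {
  hm <- simulate_sweep_haplotypes(
    sim_config(n_sites = 3000L, contig_length = 2e6,
               sweep = list(pop = "Yanbian", center = 1e6, width = 2e5,
                            founders = 1L, rare_per_bp = 2e-4),
               seed = 54))
  gm <- as_genotype_matrix(hm)
  grid <- make_windows(c("1" = 2e6), 5e4, 2e4)
  roles <- c("Yanbian", "Hanwoo", "Holstein", "Angus")
  tracks <- fst_tracks(gm, roles, grid)
  cfg <- pbs4_config("Yanbian", "Hanwoo", c("Holstein", "Angus"))
  pb <- pbs4(tracks, cfg)
  # naive recomputation straight from the five F_ST tables
  D <- function(key, i) {
    v <- tracks[[key]]$value[i]
    if (is.na(v) || v <= 0 || v >= 1) return(NA_real_)
    -log(1 - v)
  }
  for (i in seq_len(nrow(grid))) {
    naive <- (2 * D("Hanwoo|Yanbian", i) + D("Holstein|Yanbian", i) +
                D("Angus|Yanbian", i) - D("Hanwoo|Holstein", i) -
                D("Angus|Hanwoo", i)) / 4
    if (is.na(naive)) expect_true(is.na(pb$value[i]))
    else expect_equal(pb$value[i], naive, tolerance = 1e-12)
  }
  # focal-only drift (the sweep) pushes PBS4 above the genome median
  insw <- pb$start >= 9e5 & pb$end <= 11e5
  expect_gt(mean(pb$value[insw], na.rm = TRUE),
            median(pb$value, na.rm = TRUE))
})
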