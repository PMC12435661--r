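test_that("EHH matches pair-counting and is monotone non-increasing", {
  # all haplotypes identical over the contig (core included) -> EHH stays 1
  allele <- matrix(0L, 6, 9)
  hm <- make_hm(allele, seq(1e4, 9e4, by = 1e4), pop = rep("P", 3))
  prof <- ehh(hm, "P", core = 5)
  expect_true(all(prof$ehh_left == 1) && all(prof$ehh_right == 1))
  expect_equal(max(prof$dist_right), 4e4)

  # 4 haplotypes all pairwise distinct one SNP out -> EHH = 0 there
  a2 <- cbind(c(0L, 0L, 1L, 1L), c(0L, 1L, 0L, 1L))
  hm2 <- make_hm(a2, c(100L, 200L), pop = rep("P", 2))
  p2 <- ehh(hm2, "P", core = 1,
            params = ehh_params(ehh_cutoff = 0))
  expect_equal(p2$ehh_right, c(1, 0))

  # groups {3,2,1} over the interval -> (C(3,2)+C(2,2))/C(6,2) = 0.2667
  blocks <- rbind(c(0L, 0L), c(0L, 0L), c(0L, 0L),
                  c(1L, 0L), c(1L, 0L), c(1L, 1L))
  a3 <- cbind(rep(0L, 6), blocks)
  hm3 <- make_hm(a3, c(100L, 200L, 300L), pop = rep("P", 3))
  p3 <- ehh(hm3, "P", core = 1, params = ehh_params(ehh_cutoff = 0))
  expect_equal(p3$ehh_right[3], (choose(3, 2) + choose(2, 2)) / choose(6, 2))
  expect_equal(p3$ehh_right[3], oracle_ehh(a3))
  expect_equal(p3$ehh_right[2], oracle_ehh(a3[, 1:2]))

  # monotone non-increasing outward on random fixtures, EHH(0) = 1
  set.seed(61)
  for (i in 1:10) {
    a <- matrix(rbinom(16 * 40, 1, 0.5), 16, 40)
    storage.mode(a) <- "integer"
    hmr <- make_hm(a, sort(sample.int(1e5, 40)), pop = rep("P", 8))
    pr <- ehh(hmr, "P", core = 20, params = ehh_params(ehh_cutoff = 0))
    expect_equal(pr$ehh_left[1], 1)
    expect_true(all(diff(pr$ehh_left) <= 1e-12))
    expect_true(all(diff(pr$ehh_right) <= 1e-12))
  }
})

test_that("raw XP-EHH follows the integral definition and sign contracts", {
  # identical haplotype sets in both populations -> score 0
  set.seed(62)
  a <- matrix(rbinom(8 * 30, 1, 0.5), 8, 30); storage.mode(a) <- "integer"
  hm <- make_hm(rbind(a, a), sort(sample.int(2e5, 30)),
                pop = rep(c("O", "R"), each = 4))
  expect_equal(xpehh_raw(hm, "O", "R", core = 15), 0)

  # observed population fixed for one haplotype -> positive score
  hap_fixed <- matrix(rep(a[1, ], each = 8), 8)
  storage.mode(hap_fixed) <- "integer"
  hm2 <- make_hm(rbind(hap_fixed, a), sort(sample.int(2e5, 30)),
                 pop = rep(c("O", "R"), each = 4))
  expect_gt(xpehh_raw(hm2, "O", "R", core = 15), 0)

  # antisymmetry under population swap is exact
  for (core in c(5, 15, 25)) {
    expect_identical(xpehh_raw(hm2, "O", "R", core),
                     -xpehh_raw(hm2, "R", "O", core))
  }
})

test_that("worked 8+8 haplotype example matches a hand-integrated oracle", {
  # 7 SNPs at the printed positions; population O carries a long shared
  # haplotype, population R is diverse
  pos <- c(1000L, 3000L, 4500L, 5000L, 7000L, 8000L, 9500L)
  O <- rbind(
    c(0, 1, 0, 1, 0, 1, 0),
    c(0, 1, 0, 1, 0, 1, 0),
    c(0, 1, 0, 1, 0, 1, 1),
    c(0, 1, 0, 1, 0, 1, 1),
    c(0, 1, 0, 1, 1, 0, 0),
    c(0, 1, 0, 1, 1, 0, 0),
    c(1, 0, 0, 1, 0, 1, 0),
    c(1, 1, 0, 1, 0, 1, 0))
  R <- rbind(
    c(0, 0, 0, 1, 0, 0, 0),
    c(0, 1, 1, 1, 0, 1, 0),
    c(1, 0, 0, 1, 1, 0, 1),
    c(1, 1, 0, 1, 0, 0, 0),
    c(0, 0, 1, 1, 1, 1, 1),
    c(1, 1, 1, 1, 0, 1, 0),
    c(0, 1, 0, 1, 1, 0, 1),
    c(1, 0, 1, 1, 1, 1, 0))
  storage.mode(O) <- "integer"; storage.mode(R) <- "integer"
  hm <- make_hm(rbind(O, R), pos, pop = rep(c("O", "R"), each = 4))
  core <- 4L
  prm <- ehh_params(ehh_cutoff = 0.049)
  # oracle: EHH by pair counting at every offset, trapezoid by pracma
  ihh_oracle <- function(hap) {
    ihh <- 0
    for (dir in c(-1, 1)) {
      dist <- 0; eh <- 1
      j <- core
      cols <- core
      repeat {
        j <- j + dir
        if (j < 1 || j > length(pos)) break
        cols <- c(cols, j)
        e <- oracle_ehh(hap[, cols, drop = FALSE])
        if (e < prm$ehh_cutoff) break
        dist <- c(dist, abs(pos[j] - pos[core])); eh <- c(eh, e)
      }
      if (length(dist) > 1) ihh <- ihh + pracma::trapz(dist, eh)
    }
    ihh
  }
  io <- ihh_oracle(O); ir <- ihh_oracle(R)
  expect_equal(ehh(hm, "O", core, params = prm)$ihh, io, tolerance = 1e-10)
  expect_equal(ehh(hm, "R", core, params = prm)$ihh, ir, tolerance = 1e-10)
  expect_equal(xpehh_raw(hm, "O", "R", core, params = prm), log(io / ir),
               tolerance = 1e-10)
})

test_that("normalization standardizes to mean 0 / sd 1 and is idempotent", {
  expect_equal(normalize_scores(c(1, 2, 3)),
               c(-1.2247449, 0, 1.2247449), tolerance = 1e-6)
  set.seed(63)
  x <- c(rnorm(100, 5, 3), NA, NA)
  z <- normalize_scores(x)
  expect_true(all(is.na(z[101:102])))
  expect_equal(mean(z, na.rm = TRUE), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(z[1:100]^2)), 1, tolerance = 1e-12)
  expect_equal(normalize_scores(z), z, tolerance = 1e-12)
  expect_error(normalize_scores(rep(1, 5)), "variance")
  expect_error(normalize_scores(c(1, NA)), "two defined")
})

test_that("window_max keeps per-window maxima and flags empty windows", {
  w <- make_windows(c("1" = 1e5), 5e4, 5e4)
  wm <- window_max(rep("1", 3), c(100L, 200L, 300L), c(-1, 0.5, 3.2), w)
  expect_equal(wm$value[1], 3.2)
  expect_true(is.na(wm$value[2]))
})

test_that("gap rule stops integration at large inter-SNP gaps", {
  allele <- matrix(0L, 4, 3)
  allele[, 1] <- c(0L, 0L, 1L, 1L)
  hm <- make_hm(allele, c(1000L, 2000L, 500000L), pop = rep("P", 2))
  prof <- ehh(hm, "P", core = 1, params = ehh_params(ehh_cutoff = 0))
  # the 498 kb gap exceeds max_gap = 200 kb: third SNP unreachable
  expect_equal(max(prof$dist_right), 1000)
})
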