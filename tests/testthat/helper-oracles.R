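# Independent oracles used across the suite. Each is a direct, unoptimized
# transcription of the published formula or a brute-force enumeration, kept
# deliberately separate from the package's code paths.

# Exact HWE p-value by direct enumeration of heterozygote configurations:
# P(het = h | allele counts) via the factorial formula, two-sided tail of
# configurations no more probable than the observed one.
oracle_hwe_p <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  na <- 2 * n_aa + n_ab
  nb <- 2 * n_bb + n_ab
  hets <- seq(min(na, nb) %% 2, min(na, nb), by = 2)
  logp <- vapply(hets, function(h) {
    haa <- (na - h) / 2
    hbb <- (nb - h) / 2
    lfactorial(n) - lfactorial(haa) - lfactorial(h) - lfactorial(hbb) +
      h * log(2) + lfactorial(na) + lfactorial(nb) - lfactorial(2 * n)
  }, numeric(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[match(n_ab, hets)]
  sum(p[p <= obs * (1 + 1e-12)])
}

# Weir & Cockerham (1984) two-population variance components, scalar
# transcription working from genotype vectors (dosages 0/1/2, NA = missing).
oracle_wc_components <- function(gA, gB) {
  gA <- gA[!is.na(gA)]; gB <- gB[!is.na(gB)]
  n1 <- length(gA); n2 <- length(gB)
  p1 <- sum(gA) / (2 * n1); p2 <- sum(gB) / (2 * n2)
  h1 <- mean(gA == 1); h2 <- mean(gB == 1)
  r <- 2
  nbar <- mean(c(n1, n2))
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  ssq <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) * (ssq - (1 / (nbar - 1)) *
                        (pbar * (1 - pbar) - ((r - 1) / r) * ssq - hbar / 4))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * ssq -
                                ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}

# Tajima's D from a 0/1 haplotype matrix (sequences x sites), direct
# constants formula.
oracle_tajimas_d <- function(hap) {
  n <- nrow(hap)
  dac <- colSums(hap)
  seg <- dac > 0 & dac < n
  S <- sum(seg)
  if (S == 0) return(NA_real_)
  pi_sum <- sum(2 * dac[seg] * (n - dac[seg]) / (n * (n - 1)))
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  (pi_sum - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# EHH by explicit pair counting over a haplotype block (rows = haplotypes).
oracle_ehh <- function(block) {
  n <- nrow(block)
  key <- apply(block, 1, paste, collapse = "")
  sum(choose(table(key), 2)) / choose(n, 2)
}

# A tiny handwritten VCF with one SNP, one indel, one multi-allelic site and
# one missing genotype, used by the parser tests.
write_fixture_vcf <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=1,length=100000>",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2\tS3",
    "1\t100\t.\tA\tC\t.\tPASS\t.\tGT\t0/0\t0/1\t./.",
    "1\t200\t.\tAT\tA\t.\tPASS\t.\tGT\t0/0\t0/0\t0/0",
    "1\t300\t.\tG\tA,T\t.\tPASS\t.\tGT\t0/0\t1/2\t0/0"),
    path)
  path
}

write_fixture_pop_map <- function(path, samples = c("S1", "S2", "S3"),
                                  pops = c("P1", "P1", "P2")) {
  writeLines(paste(samples, pops), path)
  path
}

# Small deterministic haplotype_matrix builder for scan tests.
make_hm <- function(allele, pos, pop, chrom = "1") {
  haplotype_matrix(rep(chrom, length(pos)), pos,
                   rep("A", length(pos)), rep("C", length(pos)),
                   allele, pop)
}
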