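#' Pairwise p-distance matrix between samples
#'
#' `d(i, j)` is the mean over mutually called sites of
#' `|dosage_i - dosage_j| / 2`, i.e. the proportion of allele differences
#' between two diploids; 0 for identical samples, 1 for opposite
#' homozygotes at every site.
#'
#' @param gm A [genotype_matrix()] with >= 2 samples.
#' @return Symmetric matrix with zero diagonal, labelled by sample.
#' @export
p_distance <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  d <- gm$dosage
  n <- nrow(d)
  if (n < 2L) stop("p-distance needs at least two samples")
  out <- matrix(0, n, n, dimnames = list(rownames(d), rownames(d)))
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      ok <- !is.na(d[i, ]) & !is.na(d[j, ])
      if (!any(ok))
        stop("samples ", rownames(d)[i], " and ", rownames(d)[j],
             " share no called sites")
      out[i, j] <- out[j, i] <- mean(abs(d[i, ok] - d[j, ok]) / 2)
    }
  }
  out
}

#' Write a distance matrix in square PHYLIP format
#'
#' @param dm Symmetric labelled distance matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phylip <- function(dm, path) {
  lines <- c(sprintf("%5d", nrow(dm)),
             vapply(seq_len(nrow(dm)), function(i) {
               paste(c(sprintf("%-10s", rownames(dm)[i]),
                       sprintf("%.6f", dm[i, ])), collapse = " ")
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration with the standard Q criterion. Ties in Q are
#' broken by the lowest index pair (deterministic); negative branch lengths
#' are clamped to zero with the deficit shifted to the sister branch.
#'
#' @param dm Symmetric distance matrix with >= 3 labelled taxa.
#' @return An unrooted `phylo` tree (from \pkg{ape}) with branch lengths.
#' @export
nj_tree <- function(dm) {
  if (!isSymmetric(unname(dm), tol = 1e-8))
    stop("distance matrix must be symmetric")
  n <- nrow(dm)
  if (n < 3L) stop("neighbor joining needs at least 3 taxa")
  labels <- rownames(dm)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  nodes <- labels                 # Newick fragment per active node
  D <- dm
  while (length(nodes) > 3L) {
    N <- length(nodes)
    r <- rowSums(D)
    Q <- (N - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    # lowest index pair among minima (scan column-major upper triangle)
    best <- c(NA, NA); bestq <- Inf
    for (i in seq_len(N - 1L)) for (j in seq(i + 1L, N)) {
      if (Q[i, j] < bestq - 1e-12) { bestq <- Q[i, j]; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    bi <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (N - 2))
    bj <- D[i, j] - bi
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- bi + bj; bj <- 0 }
    newdist <- (D[i, ] + D[j, ] - D[i, j]) / 2
    merged <- sprintf("(%s:%.10g,%s:%.10g)", nodes[i], bi, nodes[j], bj)
    keep <- setdiff(seq_len(N), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], newdist[keep]),
               c(newdist[keep], 0))
    nodes <- c(nodes[keep], merged)
  }
  # closed-form star resolution for the final three nodes
  b1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  b2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  b3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  clamp <- function(x) max(x, 0)
  txt <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);", nodes[1], clamp(b1),
                 nodes[2], clamp(b2), nodes[3], clamp(b3))
  ape::read.tree(text = txt)
}

#' PCA on the genetic relationship matrix
#'
#' Builds the VanRaden-style GRM
#' `G = (1/m) * sum_sites (g - 2p)(g - 2p)' / (2p(1-p))` over polymorphic
#' sites (pooled allele frequency `p`; missing dosages mean-imputed), then
#' reports the top-`k` eigenpairs. Variance proportions are eigenvalues over
#' the trace of `G`.
#'
#' @param gm A [genotype_matrix()] without monomorphic sites (post-QC).
#' @param k Number of components (`k <= n_samples`).
#' @return List: `vectors` (samples x k), `values` (length k),
#'   `proportion` (eigenvalue / trace), `grm`.
#' @export
grm_pca <- function(gm, k = 2L) {
  stopifnot(inherits(gm, "genotype_matrix"))
  d <- gm$dosage
  n <- nrow(d)
  if (k > n) stop("k must not exceed the number of samples")
  called <- colSums(!is.na(d))
  p <- colSums(d, na.rm = TRUE) / (2 * called)
  poly <- p > 0 & p < 1
  d <- d[, poly, drop = FALSE]
  p <- p[poly]
  m <- ncol(d)
  if (m == 0L) stop("no polymorphic sites")
  z <- sweep(d, 2, 2 * p)
  z[is.na(z)] <- 0                      # mean imputation of missing dosages
  z <- sweep(z, 2, sqrt(2 * p * (1 - p)), "/")
  G <- tcrossprod(z) / m
  eg <- eigen(G, symmetric = TRUE)
  list(vectors = eg$vectors[, seq_len(k), drop = FALSE],
       values = eg$values[seq_len(k)],
       proportion = eg$values[seq_len(k)] / sum(diag(G)),
       grm = G)
}

#' Three-population f3 test with block-jackknife standard error
#'
#' Per usable site, `f3_site = (pT - pA)(pT - pB) - hT / nT` where `pT` is
#' the target allele frequency, `nT` its called allele count, and
#' `hT = pT (1 - pT) nT / (nT - 1)` the unbiased target heterozygosity (the
#' finite-sample correction of the standard estimator). `f3` is the mean
#' over sites; the standard error comes from a leave-one-block-out
#' jackknife over `block_bp` physical blocks. Significantly negative `z`
#' indicates the target is admixed between the two references.
#'
#' @param gm A [genotype_matrix()].
#' @param target,refA,refB Three distinct population labels.
#' @param block_bp Jackknife block size in bp (default 5e6).
#' @return List of class `f3_result`: `f3`, `se`, `z`, `blocks`, `n_sites`.
#' @export
f3_statistic <- function(gm, target, refA, refB, block_bp = 5e6) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (length(unique(c(target, refA, refB))) != 3L)
    stop("target and references must be three distinct populations")
  if (block_bp <= 0) stop("block_bp must be positive")
  freq <- function(pop) {
    dd <- gm$dosage[sample_rows(gm, pop), , drop = FALSE]
    nn <- 2 * colSums(!is.na(dd))
    list(p = colSums(dd, na.rm = TRUE) / nn, n = nn)
  }
  fT <- freq(target); fA <- freq(refA); fB <- freq(refB)
  usable <- fT$n >= 2 & fA$n >= 1 & fB$n >= 1 &
    is.finite(fT$p) & is.finite(fA$p) & is.finite(fB$p)
  hT <- fT$p * (1 - fT$p) * fT$n / (fT$n - 1)
  site <- (fT$p - fA$p) * (fT$p - fB$p) - hT / fT$n
  site <- site[usable]
  block <- paste0(gm$chrom, ":", (gm$pos - 1) %/% block_bp)[usable]
  blocks <- unique(block)
  if (length(blocks) < 2L) stop("need at least 2 jackknife blocks")
  f3 <- mean(site)
  loo <- vapply(blocks, function(b) mean(site[block != b]), numeric(1))
  B <- length(blocks)
  se <- sqrt((B - 1) / B * sum((loo - mean(loo))^2))
  structure(list(f3 = f3, se = se, z = f3 / se, blocks = B,
                 n_sites = length(site)), class = "f3_result")
}

#' @export
print.f3_result <- function(x, ...) {
  cat(sprintf("f3 = %.6g  SE = %.3g  Z = %.3f  (%d sites, %d blocks)\n",
              x$f3, x$se, x$z, x$n_sites, x$blocks))
  invisible(x)
}
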