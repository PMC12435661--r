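#' Windowed nucleotide diversity (pi)
#'
#' Per site, `pi_site = 2 * c_ref * c_alt / (n_c * (n_c - 1))` where `c_ref`
#' and `c_alt` are called reference/alternate allele counts in the population
#' and `n_c = c_ref + c_alt`; the window value is the sum of per-site pi over
#' the window divided by the window length (per-bp diversity, so truncated
#' terminal windows stay comparable).
#'
#' @param gm A [genotype_matrix()].
#' @param pop Population label.
#' @param windows A `window_track` from [make_windows()].
#' @return The `window_track` with per-bp pi in `value`; windows without
#'   callable sites get 0 with `n_sites = 0`.
#' @export
window_pi <- function(gm, pop, windows) {
  stopifnot(inherits(gm, "genotype_matrix"))
  d <- gm$dosage[sample_rows(gm, pop), , drop = FALSE]
  c_alt <- colSums(d, na.rm = TRUE)
  n_c <- 2 * colSums(!is.na(d))
  c_ref <- n_c - c_alt
  pi_site <- ifelse(n_c >= 2, 2 * c_ref * c_alt / (n_c * (n_c - 1)), NA)
  idx <- assign_sites(gm$chrom, gm$pos, windows)
  windows$n_sites <- vapply(idx, function(i) sum(!is.na(pi_site[i])),
                            integer(1))
  len <- windows$end - windows$start + 1
  windows$value <- vapply(seq_along(idx), function(k) {
    v <- pi_site[idx[[k]]]
    sum(v, na.rm = TRUE) / len[k]
  }, numeric(1))
  attr(windows, "stat") <- paste0("pi.", pop)
  windows
}

# Tajima (1989) normalization constants for n sequences
tajima_constants <- function(n) {
  if (n < 4) stop("Tajima's D requires at least 4 sequences")
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = e1, e2 = e2)
}

#' Windowed Tajima's D
#'
#' Standard Tajima's D per window from the segregating-site count `S` and the
#' mean pairwise difference, with the canonical `a1..e2` constants for `n`
#' sequences. Each diploid with complete data in the window's population
#' contributes two sequences; sites with any missing genotype in the
#' population are dropped. Windows with `S < min_snps` are flagged undefined
#' (`NA`), not zero.
#'
#' @inheritParams window_pi
#' @param min_snps Minimum segregating sites for a defined value (default 3).
#' @return The `window_track` with D in `value`.
#' @export
tajimas_d <- function(gm, pop, windows, min_snps = 3L) {
  stopifnot(inherits(gm, "genotype_matrix"))
  d <- gm$dosage[sample_rows(gm, pop), , drop = FALSE]
  n_seq <- 2L * nrow(d)
  if (n_seq < 4L) stop("Tajima's D requires at least 4 sequences (2 diploids)")
  cst <- tajima_constants(n_seq)
  complete <- colSums(is.na(d)) == 0L
  c_alt <- colSums(d)
  seg <- complete & c_alt > 0 & c_alt < n_seq
  # mean pairwise difference contribution per segregating site
  pi_site <- ifelse(seg, 2 * c_alt * (n_seq - c_alt) /
                      (n_seq * (n_seq - 1)), 0)
  idx <- assign_sites(gm$chrom, gm$pos, windows)
  windows$n_sites <- vapply(idx, function(i) sum(seg[i]), integer(1))
  windows$value <- vapply(idx, function(i) {
    S <- sum(seg[i])
    if (S < max(min_snps, 1)) return(NA_real_)
    pi_sum <- sum(pi_site[i])
    num <- pi_sum - S / cst$a1
    den <- sqrt(cst$e1 * S + cst$e2 * S * (S - 1))
    num / den
  }, numeric(1))
  attr(windows, "stat") <- paste0("tajd.", pop)
  windows
}

#' Diversity window parameters by gene size
#'
#' Encodes the gene-size rule used for local validation scans: genes longer
#' than 100 kb get 50 kb / 25 kb pi windows and 10 kb Tajima's D windows;
#' shorter genes get 1 kb / 0.5 kb pi windows and 5 kb Tajima's D windows.
#'
#' @param gene_length Gene span in bp (1-based inclusive length).
#' @param size_cut Gene-size cutoff in bp (default 1e5).
#' @return List with `pi_size`, `pi_step`, `tajd_size`.
#' @export
diversity_params <- function(gene_length, size_cut = 1e5) {
  if (gene_length > size_cut)
    list(pi_size = 50000L, pi_step = 25000L, tajd_size = 10000L)
  else
    list(pi_size = 1000L, pi_step = 500L, tajd_size = 5000L)
}

# windows anchored at a local region start (for gene-local scans)
local_windows <- function(chrom, from, to, size, step) {
  starts <- seq(from, to, by = step)
  w <- data.frame(chrom = chrom, start = as.integer(starts),
                  end = as.integer(pmin(starts + size - 1, to)),
                  n_sites = NA_integer_, value = NA_real_,
                  stringsAsFactors = FALSE)
  class(w) <- c("window_track", "data.frame")
  w
}

#' Local diversity scan around one gene
#'
#' Applies the gene-size window rule ([diversity_params()]) and scans
#' `gene +/- flank` with overlapping pi windows and non-overlapping Tajima's
#' D windows, for per-gene validation plots of candidate sweeps.
#'
#' @inheritParams window_pi
#' @param gene One-row data.frame with `chrom`, `start`, `end` (1-based
#'   inclusive), as returned by [read_genes()].
#' @param flank Flank in bp on each side; `NULL` (default) uses one pi window
#'   size.
#' @param min_snps_tajd Passed to [tajimas_d()].
#' @return List with `pi` and `tajd` window tracks and the chosen `params`.
#' @export
gene_region_scan <- function(gm, pop, gene, flank = NULL, min_snps_tajd = 3L) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (!gene$chrom[1] %in% gm$chrom)
    stop("gene contig '", gene$chrom[1], "' absent from genotype data")
  len <- gene$end[1] - gene$start[1] + 1
  prm <- diversity_params(len)
  if (is.null(flank)) flank <- prm$pi_size
  from <- max(1L, gene$start[1] - flank)
  to <- gene$end[1] + flank
  pi_w <- local_windows(gene$chrom[1], from, to, prm$pi_size, prm$pi_step)
  td_w <- local_windows(gene$chrom[1], from, to, prm$tajd_size, prm$tajd_size)
  list(pi = window_pi(gm, pop, pi_w),
       tajd = tajimas_d(gm, pop, td_w, min_snps = min_snps_tajd),
       params = prm)
}

#' Line plot of a per-gene diversity scan
#'
#' @param scan Result of [gene_region_scan()].
#' @param gene The gene passed to [gene_region_scan()] (drawn as a shaded
#'   span).
#' @param main Plot title.
#' @return Invisibly, `NULL`; draws on the active device.
#' @export
plot_gene_scan <- function(scan, gene = NULL, main = "") {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  mid <- function(w) (w$start + w$end) / 2
  plot(mid(scan$pi), scan$pi$value, type = "l", xlab = "position (bp)",
       ylab = expression(pi ~ "(per bp)"), main = main)
  if (!is.null(gene))
    graphics::rect(gene$start[1], graphics::par("usr")[3], gene$end[1],
                   graphics::par("usr")[4], col = grDevices::adjustcolor("grey", 0.4),
                   border = NA)
  ok <- !is.na(scan$tajd$value)
  plot(mid(scan$tajd)[ok], scan$tajd$value[ok], type = "b", pch = 16,
       cex = 0.5, xlab = "position (bp)", ylab = "Tajima's D")
  graphics::abline(h = 0, lty = 2)
  invisible(NULL)
}
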