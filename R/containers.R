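#' Genotype matrix container
#'
#' Bundles diploid genotype dosages (counts of the alternate allele, 0/1/2 or
#' `NA` for missing) for a set of samples at bi-allelic SNPs, together with
#' site coordinates and a per-sample population label.
#'
#' @param chrom Character vector of contig names, one per site.
#' @param pos Integer vector of 1-based positions, strictly increasing within
#'   each contig.
#' @param ref,alt Character vectors of reference / alternate alleles (single
#'   bases).
#' @param dosage Numeric matrix, samples x sites, entries in `{0, 1, 2, NA}`.
#' @param pop Character vector of population labels, one per sample (named by
#'   sample if `dosage` has no rownames).
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `chrom`, `pos`, `ref`, `alt`, `dosage`, `pop`.
#' @export
genotype_matrix <- function(chrom, pos, ref, alt, dosage, pop) {
  stopifnot(is.matrix(dosage))
  n_sites <- ncol(dosage)
  if (length(chrom) != n_sites || length(pos) != n_sites)
    stop("site annotation length does not match number of dosage columns")
  if (length(pop) != nrow(dosage))
    stop("every sample must have a population label")
  if (is.null(rownames(dosage)) && !is.null(names(pop)))
    rownames(dosage) <- names(pop)
  if (is.null(rownames(dosage)))
    rownames(dosage) <- paste0("S", seq_len(nrow(dosage)))
  names(pop) <- rownames(dosage)
  for (ctg in unique(chrom)) {
    p <- pos[chrom == ctg]
    if (any(diff(p) <= 0))
      stop("positions must be strictly increasing within contig ", ctg)
  }
  bad <- !(dosage %in% c(0, 1, 2) | is.na(dosage))
  if (any(bad)) stop("dosages must be 0, 1, 2 or NA")
  structure(
    list(chrom = as.character(chrom), pos = as.integer(pos),
         ref = as.character(ref), alt = as.character(alt),
         dosage = dosage, pop = pop),
    class = "genotype_matrix")
}

#' Phased haplotype matrix container
#'
#' Phased 0/1 alleles for `2 * n_samples` haplotypes at bi-allelic SNPs.
#' Haplotypes `2k - 1` and `2k` belong to sample `k`; no missing alleles are
#' allowed (phased-input contract).
#'
#' @inheritParams genotype_matrix
#' @param allele Integer matrix, haplotypes x sites, entries in `{0, 1}`.
#' @param pop Character vector of population labels, one per *sample*.
#' @param samples Optional character vector of sample names.
#'
#' @return An object of class `haplotype_matrix` with elements `chrom`, `pos`,
#'   `ref`, `alt`, `allele`, `pop` (per sample), `hap_pop` (per haplotype),
#'   `hap_sample` (sample index per haplotype).
#' @export
haplotype_matrix <- function(chrom, pos, ref, alt, allele, pop,
                             samples = NULL) {
  stopifnot(is.matrix(allele))
  if (nrow(allele) != 2L * length(pop))
    stop("expected exactly 2 haplotypes per sample")
  if (anyNA(allele)) stop("phased haplotypes cannot contain missing alleles")
  if (!all(allele %in% c(0L, 1L))) stop("alleles must be 0 or 1")
  if (is.null(samples)) samples <- names(pop)
  if (is.null(samples)) samples <- paste0("S", seq_along(pop))
  names(pop) <- samples
  hap_sample <- rep(seq_along(pop), each = 2L)
  structure(
    list(chrom = as.character(chrom), pos = as.integer(pos),
         ref = as.character(ref), alt = as.character(alt),
         allele = allele, pop = pop,
         hap_pop = pop[hap_sample], hap_sample = hap_sample),
    class = "haplotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$dosage), "samples x", length(x$pos),
      "sites on", length(unique(x$chrom)), "contig(s)\n")
  cat("populations:",
      paste(sprintf("%s (%d)", names(table(x$pop)), table(x$pop)),
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.haplotype_matrix <- function(x, ...) {
  cat("haplotype_matrix:", nrow(x$allele), "haplotypes x", length(x$pos),
      "sites on", length(unique(x$chrom)), "contig(s)\n")
  cat("populations:",
      paste(sprintf("%s (%d)", names(table(x$pop)), table(x$pop)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Collapse phased haplotypes to genotype dosages
#'
#' @param hm A [haplotype_matrix()].
#' @return A [genotype_matrix()] with dosage = sum of the two haplotype
#'   alleles per sample.
#' @export
as_genotype_matrix <- function(hm) {
  stopifnot(inherits(hm, "haplotype_matrix"))
  n <- length(hm$pop)
  dos <- hm$allele[seq(1L, 2L * n, by = 2L), , drop = FALSE] +
    hm$allele[seq(2L, 2L * n, by = 2L), , drop = FALSE]
  rownames(dos) <- names(hm$pop)
  genotype_matrix(hm$chrom, hm$pos, hm$ref, hm$alt, dos, hm$pop)
}

#' Subset a genotype matrix by site index
#' @param gm A [genotype_matrix()].
#' @param sites Integer vector of site (column) indices to keep, in order.
#' @return A [genotype_matrix()] restricted to `sites`.
#' @export
subset_sites <- function(gm, sites) {
  stopifnot(inherits(gm, "genotype_matrix"))
  genotype_matrix(gm$chrom[sites], gm$pos[sites], gm$ref[sites],
                  gm$alt[sites], gm$dosage[, sites, drop = FALSE], gm$pop)
}

# haplotype row indices for one population
hap_rows <- function(hm, pop) {
  if (!pop %in% hm$pop) stop("population '", pop, "' not present")
  which(hm$hap_pop == pop)
}

# sample row indices for one population
sample_rows <- function(gm, pop) {
  if (!pop %in% gm$pop) stop("population '", pop, "' not present")
  which(gm$pop == pop)
}
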