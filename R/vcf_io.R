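#' Read a VCF into a genotype or haplotype matrix
#'
#' Parses a VCF 4.x file (via \pkg{vcfR}), keeps bi-allelic SNP records only
#' (indels and multi-allelic sites are dropped with a message reporting the
#' count), and returns either diploid dosages or phased haplotypes.
#'
#' @param path Path to a VCF file (plain or gzipped).
#' @param pop_map Path to a two-column whitespace-delimited file mapping
#'   sample name to population label. Every VCF sample must appear.
#' @param phased If `TRUE`, require `|`-separated genotypes at every retained
#'   site and return a [haplotype_matrix()]; otherwise return a
#'   [genotype_matrix()] (missing genotypes allowed).
#'
#' @return A [genotype_matrix()] or [haplotype_matrix()].
#' @export
read_vcf <- function(path, pop_map, phased = FALSE) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  pops <- read_pop_map(pop_map)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  is_snp <- !is.na(alt) & nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_drop <- sum(!is_snp)
  if (n_drop > 0)
    message("read_vcf: dropped ", n_drop,
            " non-SNP or multi-allelic record(s)")
  keep <- which(is_snp)
  if (length(keep) == 0L) stop("no bi-allelic SNP records in ", path)
  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  samples <- colnames(gt)
  missing_samples <- setdiff(samples, names(pops))
  if (length(missing_samples) > 0)
    stop("sample(s) absent from population map: ",
         paste(missing_samples, collapse = ", "))
  chrom <- fix[keep, "CHROM"]
  pos <- as.integer(fix[keep, "POS"])
  ref <- ref[keep]; alt <- alt[keep]
  pop <- pops[samples]

  if (phased) {
    unph <- which(!is.na(gt) & !grepl("|", gt, fixed = TRUE), arr.ind = TRUE)
    if (anyNA(gt) || nrow(unph) > 0) {
      bad <- if (nrow(unph) > 0) unph[1, 1] else which(is.na(gt), arr.ind = TRUE)[1, 1]
      stop("unphased or missing genotype at ", chrom[bad], ":", pos[bad],
           " but phased = TRUE")
    }
    a1 <- suppressWarnings(as.integer(substr(gt, 1L, 1L)))
    a2 <- suppressWarnings(as.integer(substr(gt, 3L, 3L)))
    if (anyNA(a1) || anyNA(a2))
      stop("malformed phased genotype encountered")
    n_sites <- length(keep); n_samp <- length(samples)
    allele <- matrix(0L, nrow = 2L * n_samp, ncol = n_sites)
    # gt is sites x samples; interleave the two alleles per sample
    allele[seq(1L, 2L * n_samp, 2L), ] <- t(matrix(a1, n_sites, n_samp))
    allele[seq(2L, 2L * n_samp, 2L), ] <- t(matrix(a2, n_sites, n_samp))
    haplotype_matrix(chrom, pos, ref, alt, allele, pop, samples = samples)
  } else {
    core <- sub(":.*", "", gt)
    dos <- matrix(NA_real_, nrow = length(samples), ncol = length(keep),
                  dimnames = list(samples, NULL))
    counted <- vapply(strsplit(ifelse(is.na(core), "", core), "[/|]"),
                      function(a) {
                        a <- suppressWarnings(as.integer(a))
                        if (length(a) != 2L || anyNA(a)) NA_real_ else sum(a)
                      }, numeric(1))
    dos[] <- t(matrix(counted, nrow = length(keep)))
    genotype_matrix(chrom, pos, ref, alt, dos, pop)
  }
}

#' Read a two-column sample-to-population map
#'
#' @param path Whitespace-delimited file: sample name, population label.
#' @return Named character vector of population labels.
#' @export
read_pop_map <- function(path) {
  if (!file.exists(path)) stop("population map not found: ", path)
  tab <- read.table(path, header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("sample", "population"))
  setNames(as.character(tab$population), tab$sample)
}

#' Write genotypes or haplotypes to a plain-text VCF
#'
#' Emits a minimal VCF 4.2 file with GT-only genotype fields. Haplotype
#' matrices are written phased (`|` separator); genotype matrices unphased
#' (`/`, missing as `./.`, heterozygotes as `0/1`).
#'
#' @param x A [genotype_matrix()] or [haplotype_matrix()].
#' @param path Output file path.
#' @param contig_lengths Optional named vector of contig lengths for the
#'   header; defaults to the maximum observed position per contig.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path, contig_lengths = NULL) {
  phased <- inherits(x, "haplotype_matrix")
  if (!phased && !inherits(x, "genotype_matrix"))
    stop("x must be a genotype_matrix or haplotype_matrix")
  if (is.null(contig_lengths)) {
    contig_lengths <- tapply(x$pos, x$chrom, max)
  }
  hdr <- c("##fileformat=VCFv4.2",
           "##source=sweepscan",
           sprintf("##contig=<ID=%s,length=%d>",
                   names(contig_lengths), as.integer(contig_lengths)),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", names(x$pop)), collapse = "\t"))
  n_sites <- length(x$pos)
  if (phased) {
    n <- length(x$pop)
    h1 <- x$allele[seq(1L, 2L * n, 2L), , drop = FALSE]
    h2 <- x$allele[seq(2L, 2L * n, 2L), , drop = FALSE]
    gt <- matrix(paste0(h1, "|", h2), nrow = n)
  } else {
    d <- x$dosage
    gt <- matrix("./.", nrow = nrow(d), ncol = ncol(d))
    gt[!is.na(d) & d == 0] <- "0/0"
    gt[!is.na(d) & d == 1] <- "0/1"
    gt[!is.na(d) & d == 2] <- "1/1"
  }
  body <- paste(x$chrom, x$pos, ".", x$ref, x$alt, ".", "PASS", ".", "GT",
                apply(gt, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write a population map file
#' @param pop Named character vector (sample -> population).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pop_map <- function(pop, path) {
  writeLines(paste(names(pop), pop), path)
  invisible(path)
}

#' Read gene records from BED or GFF3
#'
#' The format is chosen by file extension (`.bed` vs `.gff`/`.gff3`). BED
#' intervals (0-based half-open) are normalized to the package-wide 1-based
#' inclusive convention, so BED `chr1 99 200` becomes `start = 100, end = 200`.
#' From GFF3 only `gene` features are kept; `gene_id`/`ID` and `Name` are
#' pulled from the attribute column.
#'
#' @param path Path to a `.bed`, `.gff` or `.gff3` file.
#' @return A data.frame with columns `gene_id`, `gene_name`, `chrom`,
#'   `start`, `end`, `strand` (1-based inclusive coordinates).
#' @export
read_genes <- function(path) {
  if (!file.exists(path)) stop("gene file not found: ", path)
  ext <- tolower(sub(".*\\.", "", path))
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  out <- list()
  if (ext == "bed") {
    for (i in idx) {
      f <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
      if (length(f) < 3L)
        stop("malformed BED line ", i, " in ", path)
      s0 <- suppressWarnings(as.integer(f[2]))
      e0 <- suppressWarnings(as.integer(f[3]))
      if (is.na(s0) || is.na(e0) || e0 < s0)
        stop("malformed BED line ", i, " in ", path)
      out[[length(out) + 1L]] <- data.frame(
        gene_id = if (length(f) >= 4L) f[4] else paste0("bed_", i),
        gene_name = if (length(f) >= 4L) f[4] else "",
        chrom = f[1], start = s0 + 1L, end = e0,
        strand = if (length(f) >= 6L) f[6] else "+",
        stringsAsFactors = FALSE)
    }
  } else if (ext %in% c("gff", "gff3")) {
    for (i in idx) {
      f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
      if (length(f) < 9L)
        stop("malformed GFF3 line ", i, " in ", path)
      if (tolower(f[3]) != "gene") next
      s <- suppressWarnings(as.integer(f[4]))
      e <- suppressWarnings(as.integer(f[5]))
      if (is.na(s) || is.na(e) || e < s)
        stop("malformed GFF3 line ", i, " in ", path)
      attr_field <- f[9]
      get_attr <- function(key) {
        m <- regmatches(attr_field,
                        regexec(paste0("(?:^|;)\\s*", key, "=([^;]+)"),
                                attr_field))[[1]]
        if (length(m) == 2L) m[2] else ""
      }
      gid <- get_attr("gene_id")
      if (!nzchar(gid)) gid <- get_attr("ID")
      if (!nzchar(gid)) gid <- paste0("gene_", i)
      out[[length(out) + 1L]] <- data.frame(
        gene_id = gid, gene_name = get_attr("Name"),
        chrom = f[1], start = s, end = e, strand = f[7],
        stringsAsFactors = FALSE)
    }
  } else {
    stop("unrecognized gene file extension: .", ext,
         " (expected .bed, .gff or .gff3)")
  }
  if (length(out) == 0L)
    return(data.frame(gene_id = character(), gene_name = character(),
                      chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Convert between BED and 1-based inclusive interval conventions
#'
#' @param start,end Interval bounds.
#' @return A two-column data.frame (`start`, `end`) in the other convention.
#' @export
bed_to_inclusive <- function(start, end) {
  data.frame(start = start + 1L, end = end)
}

#' @rdname bed_to_inclusive
#' @export
inclusive_to_bed <- function(start, end) {
  data.frame(start = start - 1L, end = end)
}
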