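#' Scan parameters for EHH/XP-EHH
#'
#' @param ehh_cutoff EHH value below which outward extension stops
#'   (default 0.05).
#' @param max_extend Maximum extension distance from the core in bp
#'   (default 1e6).
#' @param max_gap Inter-SNP gap in bp beyond which extension stops at the
#'   gap (default 2e5).
#' @param maf_min Cores with pooled minor allele frequency below this are
#'   skipped (default 0.05, matching upstream site QC).
#' @return List of class `ehh_params`.
#' @export
ehh_params <- function(ehh_cutoff = 0.05, max_extend = 1e6, max_gap = 2e5,
                       maf_min = 0.05) {
  structure(list(ehh_cutoff = ehh_cutoff, max_extend = max_extend,
                 max_gap = max_gap, maf_min = maf_min),
            class = "ehh_params")
}

# haplotype sub-matrix (integer) for one population; single contig enforced
hap_for_pop <- function(hm, pop) {
  stopifnot(inherits(hm, "haplotype_matrix"))
  if (length(unique(hm$chrom)) != 1L)
    stop("haplotype scans operate on one contig at a time")
  storage.mode(hm$allele) <- "integer"
  hm$allele[hap_rows(hm, pop), , drop = FALSE]
}

#' Extended haplotype homozygosity profile around a core SNP
#'
#' EHH at extension set `E` is the probability that two random haplotypes
#' from the population are identical over `{core} U E`:
#' `sum_g C(n_g, 2) / C(n, 2)`. Extension proceeds outward SNP by SNP until
#' EHH drops below `ehh_cutoff`, the distance exceeds `max_extend`, an
#' inter-SNP gap exceeds `max_gap`, or the chromosome ends. Physical (bp)
#' distance is used throughout.
#'
#' @param hm A [haplotype_matrix()] (one contig).
#' @param pop Population label (>= 2 haplotypes).
#' @param core Site index of the core SNP.
#' @param direction `"both"`, `"left"` or `"right"`.
#' @param params An [ehh_params()].
#' @return List of class `ehh_profile` with `core`, per-direction `dist`
#'   (bp offsets, 0 first) and `ehh` vectors, and `ihh` (trapezoidal
#'   integral over both requested directions).
#' @export
ehh <- function(hm, pop, core, direction = c("both", "left", "right"),
                params = ehh_params()) {
  direction <- match.arg(direction)
  hap <- hap_for_pop(hm, pop)
  if (nrow(hap) < 2L) stop("population must contribute >= 2 haplotypes")
  prof <- ehh_profile_cpp(hap, hm$pos, core, params$ehh_cutoff,
                          params$max_extend, params$max_gap)
  out <- list(core = core, pop = pop)
  if (direction %in% c("both", "left")) {
    out$dist_left <- prof$dist_left; out$ehh_left <- prof$ehh_left
  }
  if (direction %in% c("both", "right")) {
    out$dist_right <- prof$dist_right; out$ehh_right <- prof$ehh_right
  }
  out$ihh <- switch(direction,
    both = prof$ihh,
    left = trapz_(prof$dist_left, prof$ehh_left),
    right = trapz_(prof$dist_right, prof$ehh_right))
  class(out) <- "ehh_profile"
  out
}

trapz_ <- function(x, y) {
  if (length(x) < 2L) return(0)
  sum(0.5 * (y[-1] + y[-length(y)]) * diff(x))
}

#' Raw XP-EHH score at one core SNP
#'
#' `ln(iHH_obs / iHH_ref)` where iHH is the trapezoidal integral of the EHH
#' decay over physical distance (both directions summed, truncated at the
#' EHH cutoff independently per population). Positive scores indicate longer
#' haplotype homozygosity in the observed (focal) population.
#'
#' @inheritParams ehh
#' @param pop_obs,pop_ref Observed (focal) and reference population labels.
#' @return The raw score, or `NA` (flagged undefined) if `iHH_ref = 0`.
#' @export
xpehh_raw <- function(hm, pop_obs, pop_ref, core, params = ehh_params()) {
  io <- ehh(hm, pop_obs, core, params = params)$ihh
  ir <- ehh(hm, pop_ref, core, params = params)$ihh
  if (ir == 0 || io == 0) return(NA_real_)
  log(io) - log(ir)
}

#' Genome-wide XP-EHH scan
#'
#' Scores every eligible core SNP (pooled MAF >= `maf_min`; monomorphic
#' cores skipped) with the raw XP-EHH statistic, then standardizes
#' genome-wide with [normalize_scores()] in a single bin.
#'
#' @inheritParams xpehh_raw
#' @return Data.frame: `chrom`, `pos`, `raw`, `normalized` (one row per
#'   scored core; skipped cores are absent).
#' @export
xpehh_scan <- function(hm, pop_obs, pop_ref, params = ehh_params()) {
  hap_o <- hap_for_pop(hm, pop_obs)
  hap_r <- hap_for_pop(hm, pop_ref)
  both <- rbind(hap_o, hap_r)
  af <- colMeans(both)
  maf <- pmin(af, 1 - af)
  cores <- which(maf >= params$maf_min & maf > 0)
  if (length(cores) == 0L) stop("no eligible core SNPs")
  io <- ihh_scan_cpp(hap_o, hm$pos, cores, params$ehh_cutoff,
                     params$max_extend, params$max_gap)
  ir <- ihh_scan_cpp(hap_r, hm$pos, cores, params$ehh_cutoff,
                     params$max_extend, params$max_gap)
  raw <- ifelse(io > 0 & ir > 0, log(io / ir), NA_real_)
  data.frame(chrom = hm$chrom[cores], pos = hm$pos[cores], raw = raw,
             normalized = normalize_scores(raw))
}

#' Standardize scores genome-wide
#'
#' `z = (x - mean) / sd` over all defined scores in a single genome-wide
#' bin, with the population (divide-by-n) standard deviation. Undefined
#' entries stay `NA` and are excluded from the moments.
#'
#' @param x Numeric scores (NA allowed).
#' @return Standardized scores with mean 0 and sd 1 over defined entries.
#' @export
normalize_scores <- function(x) {
  ok <- !is.na(x)
  if (sum(ok) < 2L) stop("need at least two defined scores to normalize")
  m <- mean(x[ok])
  s <- sqrt(mean((x[ok] - m)^2))
  if (s == 0) stop("zero variance: scores cannot be standardized")
  (x - m) / s
}

#' Per-window maximum of a per-SNP score track
#'
#' @param chrom,pos,score Per-SNP coordinates and (normalized) scores.
#' @param windows A `window_track`, typically 50-kb non-overlapping.
#' @return The `window_track` with the in-window maximum in `value`;
#'   windows without scored SNPs are `NA`.
#' @export
window_max <- function(chrom, pos, score, windows) {
  window_summarize(chrom, pos, score, windows, fun = max,
                   stat = "window_max")
}

#' @export
print.ehh_profile <- function(x, ...) {
  cat("ehh_profile: core site", x$core, "in", x$pop, "\n")
  if (!is.null(x$dist_left))
    cat("  left:", length(x$dist_left), "points to -",
        max(x$dist_left), "bp\n")
  if (!is.null(x$dist_right))
    cat("  right:", length(x$dist_right), "points to", max(x$dist_right),
        "bp\n")
  cat("  iHH:", format(x$ihh), "\n")
  invisible(x)
}
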