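#' Per-site Weir-Cockerham variance components for two populations
#'
#' Computes the 1984 variance components `a` (among populations), `b` (among
#' individuals within populations) and `c` (within individuals) per site from
#' diploid sample sizes, alternate-allele frequencies and observed
#' heterozygote frequencies, plus the per-site estimate
#' `theta = a / (a + b + c)`. Sites with fewer than two called diploids in
#' either population are skipped (`NA`).
#'
#' @param gm A [genotype_matrix()].
#' @param popA,popB Population labels (order does not affect `theta`).
#' @return A data.frame with one row per site: `chrom`, `pos`, `a`, `b`,
#'   `c`, `theta`.
#' @export
wc_fst_site <- function(gm, popA, popB) {
  stopifnot(inherits(gm, "genotype_matrix"))
  dA <- gm$dosage[sample_rows(gm, popA), , drop = FALSE]
  dB <- gm$dosage[sample_rows(gm, popB), , drop = FALSE]
  nA <- colSums(!is.na(dA))
  nB <- colSums(!is.na(dB))
  pA <- colSums(dA, na.rm = TRUE) / (2 * nA)
  pB <- colSums(dB, na.rm = TRUE) / (2 * nB)
  hA <- colSums(dA == 1, na.rm = TRUE) / nA
  hB <- colSums(dB == 1, na.rm = TRUE) / nB
  r <- 2
  nbar <- (nA + nB) / r
  nc <- (r * nbar - (nA^2 + nB^2) / (r * nbar)) / (r - 1)
  pbar <- (nA * pA + nB * pB) / (r * nbar)
  s2 <- (nA * (pA - pbar)^2 + nB * (pB - pbar)^2) / ((r - 1) * nbar)
  hbar <- (nA * hA + nB * hB) / (r * nbar)
  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  usable <- nA >= 2 & nB >= 2
  a[!usable] <- NA; b[!usable] <- NA; cc[!usable] <- NA
  tot <- a + b + cc
  theta <- ifelse(!is.na(tot) & tot != 0, a / tot, NA)
  data.frame(chrom = gm$chrom, pos = gm$pos, a = a, b = b, c = cc,
             theta = theta)
}

#' Windowed Weir-Cockerham F_ST (ratio of sums)
#'
#' Window F_ST is `sum(a) / sum(a + b + c)` over in-window sites (the
#' "weighted" estimator). Windows with no usable sites are `NA`. Windows
#' with F_ST <= 0 are kept in the track; [pbs4()] treats them as undefined
#' (negative or missing values are excluded from branch-length space).
#'
#' @param comp Per-site components from [wc_fst_site()].
#' @param windows A `window_track` from [make_windows()].
#' @param estimator `"ratio_of_sums"` (default) or `"mean_of_ratios"`.
#' @return The `window_track` with window F_ST in `value`.
#' @export
wc_fst_window <- function(comp, windows,
                          estimator = c("ratio_of_sums", "mean_of_ratios")) {
  estimator <- match.arg(estimator)
  idx <- assign_sites(comp$chrom, comp$pos, windows)
  usable <- !is.na(comp$a)
  windows$n_sites <- vapply(idx, function(i) sum(usable[i]), integer(1))
  windows$value <- vapply(idx, function(i) {
    i <- i[usable[i]]
    if (length(i) == 0L) return(NA_real_)
    if (estimator == "ratio_of_sums") {
      den <- sum(comp$a[i] + comp$b[i] + comp$c[i])
      if (den == 0) return(NA_real_)
      sum(comp$a[i]) / den
    } else {
      mean(comp$theta[i], na.rm = TRUE)
    }
  }, numeric(1))
  attr(windows, "stat") <- "fst"
  windows
}

#' Log branch length from pairwise F_ST
#'
#' `D = -ln(1 - fst)`, defined for `0 <= fst < 1`. Negative F_ST must be
#' excluded by the caller (undefined branch); `fst = 1` gives an infinite
#' branch and errors.
#'
#' @param fst Numeric vector of pairwise F_ST values in `[0, 1)`.
#' @return Numeric vector of branch lengths `D >= 0`.
#' @export
branch_length <- function(fst) {
  bad <- !is.na(fst) & (fst < 0)
  if (any(bad)) stop("negative F_ST: exclude before transforming")
  if (any(!is.na(fst) & fst >= 1))
    stop("F_ST >= 1 gives an infinite branch length")
  -log(1 - fst)
}

#' Four-population branch-statistic configuration
#'
#' @param focal Focal population (the scanned lineage).
#' @param sister Closely related population whose branch term is doubled.
#' @param outgroups Character vector of the two outgroup labels.
#' @return List of class `pbs4_config`.
#' @export
pbs4_config <- function(focal, sister, outgroups) {
  labs <- c(focal, sister, outgroups)
  if (length(outgroups) != 2L || length(unique(labs)) != 4L)
    stop("PBS4 needs four distinct population roles (focal, sister, 2 outgroups)")
  structure(list(focal = focal, sister = sister, outgroups = outgroups),
            class = "pbs4_config")
}

# canonical name of an unordered population pair
pair_key <- function(a, b) paste(sort(c(a, b)), collapse = "|")

#' Compute all pairwise windowed F_ST tracks needed for PBS4
#'
#' @param gm A [genotype_matrix()].
#' @param pops Population labels (all pairs are computed).
#' @param windows Shared `window_track` grid.
#' @param estimator Passed to [wc_fst_window()].
#' @return Named list of `window_track`s keyed by `"A|B"` (sorted labels).
#' @export
fst_tracks <- function(gm, pops, windows,
                       estimator = "ratio_of_sums") {
  pairs <- utils::combn(sort(pops), 2, simplify = FALSE)
  out <- lapply(pairs, function(pr) {
    comp <- wc_fst_site(gm, pr[1], pr[2])
    wc_fst_window(comp, windows, estimator = estimator)
  })
  names(out) <- vapply(pairs, function(pr) pair_key(pr[1], pr[2]),
                       character(1))
  out
}

#' Four-population branch statistic (PBS4) per window
#'
#' `PBS4 = (2 D[focal,sister] + D[focal,out1] + D[focal,out2]
#'          - D[sister,out1] - D[sister,out2]) / 4`,
#' with `D = -ln(1 - F_ST)` per window. A window where any of the five
#' required pairwise F_ST values is missing or non-positive is flagged
#' undefined (`NA`), not zero (`exclude = "window"`); with
#' `exclude = "pair"` only negative values are clamped undefined per pair
#' and the window is dropped only if a required pair is unusable.
#'
#' @param tracks Named list of pairwise F_ST `window_track`s on one shared
#'   grid, keyed as produced by [fst_tracks()].
#' @param cfg A [pbs4_config()].
#' @param exclude `"window"` (default): drop the whole window when any of the
#'   five pairs is negative/missing.
#' @return A `window_track` with PBS4 in `value`.
#' @export
pbs4 <- function(tracks, cfg, exclude = c("window", "pair")) {
  exclude <- match.arg(exclude)
  stopifnot(inherits(cfg, "pbs4_config"))
  need <- c(pair_key(cfg$focal, cfg$sister),
            pair_key(cfg$focal, cfg$outgroups[1]),
            pair_key(cfg$focal, cfg$outgroups[2]),
            pair_key(cfg$sister, cfg$outgroups[1]),
            pair_key(cfg$sister, cfg$outgroups[2]))
  miss <- setdiff(need, names(tracks))
  if (length(miss) > 0)
    stop("missing pairwise F_ST track(s): ", paste(miss, collapse = ", "))
  grid <- tracks[[need[1]]]
  vals <- vapply(need, function(k) {
    tr <- tracks[[k]]
    if (nrow(tr) != nrow(grid) || any(tr$start != grid$start) ||
        any(tr$chrom != grid$chrom))
      stop("pairwise F_ST tracks are not on a shared window grid")
    tr$value
  }, numeric(nrow(grid)))
  if (!is.matrix(vals)) vals <- matrix(vals, nrow = 1L)  # single-window grid
  if (exclude == "pair") {
    # negative pairwise values clamped to a zero branch; only truly missing
    # pairs invalidate the window
    usable <- !is.na(vals) & vals < 1
    D <- matrix(NA_real_, nrow(vals), ncol(vals))
    D[usable] <- -log(1 - pmax(vals[usable], 0))
  } else {
    usable <- !is.na(vals) & vals > 0 & vals < 1
    D <- matrix(NA_real_, nrow(vals), ncol(vals))
    D[usable] <- -log(1 - vals[usable])
  }
  ok <- rowSums(usable) == 5L
  out <- grid
  out$value <- NA_real_
  out$value[ok] <- (2 * D[ok, 1] + D[ok, 2] + D[ok, 3] -
                      D[ok, 4] - D[ok, 5]) / 4
  out$n_sites <- tracks[[need[1]]]$n_sites
  attr(out, "stat") <- paste0("pbs4.", cfg$focal)
  out
}
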