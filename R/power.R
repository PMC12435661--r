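#' Replicate power experiment for the planted-sweep pipeline
#'
#' Runs the complete scan on seeded sweep simulations and records, per
#' replicate, whether the window containing the sweep center reaches the
#' empirical top-`q` for PBS4 and for XP-EHH (run against each reference
#' population; the union across references mirrors a multi-reference study
#' design), together with the focal-population diversity signature inside
#' the sweep (per-bp pi relative to the genome background, mean windowed
#' Tajima's D).
#'
#' @param n_rep Number of replicates.
#' @param seed Base seed; replicate `r` uses `seed + r`.
#' @param config A [sim_config()] template (its `seed` is overridden).
#' @param references Reference populations for the XP-EHH runs.
#' @param sister Sister population for the PBS4 role assignment (the
#'   remaining two populations become the outgroups).
#' @param q Upper-tail fraction for outlier calling.
#' @param qc Apply [filter_sites()] before the F_ST stage.
#' @return Data.frame with one row per replicate: `pbs4_hit`, `xpehh_hit`
#'   (union over references), one `xpehh_hit_<ref>` column per reference,
#'   `pi_ratio` (sweep / background), `tajd_sweep`.
#' @export
evaluate_sweep_power <- function(n_rep = 50L, seed = 1L,
                                 config = sim_config(),
                                 references = c("Hanwoo", "Holstein",
                                                "Angus"),
                                 sister = "Hanwoo", q = 0.01, qc = TRUE) {
  stopifnot(inherits(config, "sim_config"), !is.null(config$sweep))
  focal <- config$sweep$pop
  others <- setdiff(names(config$pops), focal)
  if (length(others) != 3L)
    stop("the experiment expects the four-population design")
  if (!sister %in% others) stop("sister must be a non-focal population")
  outg <- setdiff(others, sister)
  cl <- setNames(config$contig_length, config$contig)
  out <- data.frame(pbs4_hit = logical(n_rep), xpehh_hit = logical(n_rep),
                    pi_ratio = numeric(n_rep), tajd_sweep = numeric(n_rep))
  for (ref in references) out[[paste0("xpehh_hit_", ref)]] <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    cfg <- config
    cfg$seed <- as.integer(seed + r)
    hm <- simulate_sweep_haplotypes(cfg)
    tr <- attr(hm, "truth")
    ctr <- tr$sweep$center
    gm <- as_genotype_matrix(hm)
    gmq <- if (qc) filter_sites(gm)$gm else gm
    grid <- make_windows(cl, 50000, 20000)
    tracks <- fst_tracks(gmq, c(focal, others), grid)
    pb <- pbs4(tracks, pbs4_config(focal, sister, outg))
    sel <- empirical_threshold(pb, q)$selected
    out$pbs4_hit[r] <- any(sel$start <= ctr & sel$end >= ctr)
    xp_grid <- make_windows(cl, 50000, 50000)
    for (ref in references) {
      scan <- xpehh_scan(hm, focal, ref)
      wm <- window_max(scan$chrom, scan$pos, scan$normalized, xp_grid)
      selx <- empirical_threshold(wm, q)$selected
      out[[paste0("xpehh_hit_", ref)]][r] <-
        any(selx$start <= ctr & selx$end >= ctr)
    }
    out$xpehh_hit[r] <- any(vapply(references, function(ref)
      out[[paste0("xpehh_hit_", ref)]][r], logical(1)))
    w50 <- make_windows(cl, 50000, 50000)
    pit <- window_pi(gm, focal, w50)
    insw <- pit$start >= tr$sweep$lo & pit$end <= tr$sweep$hi
    out$pi_ratio[r] <- mean(pit$value[insw]) / mean(pit$value[!insw])
    td <- tajimas_d(gm, focal, w50)
    out$tajd_sweep[r] <- mean(td$value[insw], na.rm = TRUE)
  }
  out
}
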