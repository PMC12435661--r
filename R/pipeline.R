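#' Pipeline configuration
#'
#' Ties the scan stages together: population roles, window geometry per
#' statistic, the outlier quantile, and the seed. All randomness in a run
#' funnels through `seed`.
#'
#' @param focal Focal (scanned) population.
#' @param sister Sister population (doubled PBS4 branch term).
#' @param outgroups Two outgroup labels.
#' @param references Reference populations for the XP-EHH runs (defaults to
#'   all non-focal roles).
#' @param fst_size,fst_step F_ST/PBS4 window geometry in bp (50 kb / 20 kb).
#' @param xpehh_size XP-EHH window size in bp (50 kb, non-overlapping).
#' @param top_q Upper-tail fraction for outlier calling (default 0.01).
#' @param qc Apply [filter_sites()] to the dosage data before the F_ST
#'   stage (default TRUE).
#' @param seed Integer seed.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(focal = "Yanbian", sister = "Hanwoo",
                            outgroups = c("Holstein", "Angus"),
                            references = NULL,
                            fst_size = 50000L, fst_step = 20000L,
                            xpehh_size = 50000L, top_q = 0.01,
                            qc = TRUE, seed = 1L) {
  roles <- c(focal, sister, outgroups)
  if (length(unique(roles)) != 4L)
    stop("PBS4 role assignment needs four distinct populations ",
         "(focal, sister, two outgroups)")
  if (is.null(references)) references <- c(sister, outgroups)
  structure(list(focal = focal, sister = sister, outgroups = outgroups,
                 references = references, fst_size = fst_size,
                 fst_step = fst_step, xpehh_size = xpehh_size,
                 top_q = top_q, qc = qc, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full selection-scan pipeline
#'
#' Stages: (1) optional site QC on the dosage view; (2) all pairwise
#' windowed Weir-Cockerham F_ST on the shared 50 kb / 20 kb grid and PBS4;
#' (3) per-reference XP-EHH with genome-wide normalization and 50-kb
#' window maxima; (4) empirical top-quantile outlier calling per scan;
#' (5) gene annotation and the merged candidate table. Every interchange
#' table is written as TSV under `outdir` (`fst/`, `pbs4/`, `xpehh/`,
#' `selected/`, `candidates.tsv`, `run_log.txt`). Deterministic given the
#' inputs and config.
#'
#' @param hm A [haplotype_matrix()] (phased input contract), e.g. from
#'   [read_vcf()] with `phased = TRUE` or [simulate_sweep_haplotypes()].
#' @param genes Gene table from [read_genes()] (may have zero rows).
#' @param config A [pipeline_config()].
#' @param outdir Output directory (created if missing).
#' @param contig_lengths Named vector of contig lengths; defaults to the
#'   maximum observed position per contig.
#' @param extra_tracks Optional named list of externally computed
#'   `window_track`s (e.g. composite-likelihood scores read with
#'   [read_window_track()]); each is thresholded and annotated identically.
#' @return List with the computed tracks, selected regions and candidate
#'   table (also written to `outdir`).
#' @export
run_pipeline <- function(hm, genes, config = pipeline_config(),
                         outdir = tempfile("sweepscan_run_"),
                         contig_lengths = NULL, extra_tracks = list()) {
  stopifnot(inherits(hm, "haplotype_matrix"),
            inherits(config, "pipeline_config"))
  pops <- unique(hm$pop)
  roles <- c(config$focal, config$sister, config$outgroups)
  missing_roles <- setdiff(roles, pops)
  if (length(missing_roles) > 0)
    stop("role population(s) absent from data: ",
         paste(missing_roles, collapse = ", "))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  for (sub in c("fst", "pbs4", "xpehh", "selected"))
    dir.create(file.path(outdir, sub), showWarnings = FALSE)
  log_lines <- c(paste("sweepscan", as.character(utils::packageVersion("sweepscan"))),
                 paste("config:", paste(deparse(unclass(config)), collapse = " ")),
                 paste("config_hash:",
                       sum(utf8ToInt(paste(deparse(unclass(config)),
                                           collapse = "")))))
  if (is.null(contig_lengths))
    contig_lengths <- tapply(hm$pos, hm$chrom, max)

  gm <- as_genotype_matrix(hm)
  if (isTRUE(config$qc)) {
    qc <- filter_sites(gm, qc_thresholds())
    gm <- qc$gm
    log_lines <- c(log_lines,
                   sprintf("qc: removed hwe=%d maf=%d callrate=%d retained=%d",
                           qc$report$removed[1], qc$report$removed[2],
                           qc$report$removed[3], qc$report$retained[1]))
  }

  # F_ST + PBS4 on the shared grid
  fst_grid <- make_windows(contig_lengths, config$fst_size, config$fst_step)
  tracks <- fst_tracks(gm, roles, fst_grid)
  for (k in names(tracks))
    write_window_track(tracks[[k]],
                       file.path(outdir, "fst",
                                 paste0("fst_", gsub("\\|", "_", k), ".tsv")))
  pbs_track <- pbs4(tracks, pbs4_config(config$focal, config$sister,
                                        config$outgroups))
  write_window_track(pbs_track, file.path(outdir, "pbs4", "pbs4.tsv"))

  # XP-EHH per reference population
  xp_grid <- make_windows(contig_lengths, config$xpehh_size,
                          config$xpehh_size)
  xp_tracks <- list()
  for (ref in config$references) {
    scan <- xpehh_scan(hm, config$focal, ref)
    write.table(scan, file.path(outdir, "xpehh",
                                paste0("xpehh_", ref, "_persnp.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    wt <- window_max(scan$chrom, scan$pos, scan$normalized, xp_grid)
    xp_tracks[[ref]] <- wt
    write_window_track(wt, file.path(outdir, "xpehh",
                                     paste0("xpehh_", ref, "_windowmax.tsv")))
  }

  # top-quantile outlier calling + annotation
  region_sets <- list()
  all_tracks <- c(list(PBS4 = pbs_track),
                  setNames(xp_tracks, paste0("XP-EHH_", names(xp_tracks))),
                  extra_tracks)
  refs <- c(NA_character_, names(xp_tracks),
            rep(NA_character_, length(extra_tracks)))
  for (i in seq_along(all_tracks)) {
    nm <- names(all_tracks)[i]
    thr <- empirical_threshold(all_tracks[[i]], config$top_q)
    regions <- sweep_regions(thr$selected, genes, method = nm,
                             reference = refs[i])
    region_sets[[nm]] <- regions
    write.table(regions, file.path(outdir, "selected",
                                   paste0("selected_", nm, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    log_lines <- c(log_lines,
                   sprintf("%s: N=%d selected=%d threshold=%.6g annotated=%d genes=%d",
                           nm, thr$n_defined, thr$k, thr$threshold,
                           annotate_regions(thr$selected, genes)$annotated_regions,
                           length(annotate_regions(thr$selected, genes)$genes)))
  }
  candidates <- merge_candidates(region_sets)
  write.table(candidates, file.path(outdir, "candidates.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(log_lines, file.path(outdir, "run_log.txt"))
  list(gm = gm, fst = tracks, pbs4 = pbs_track, xpehh = xp_tracks,
       regions = region_sets, candidates = candidates, outdir = outdir,
       log = log_lines)
}
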