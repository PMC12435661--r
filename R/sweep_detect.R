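#' Empirical top-quantile outlier threshold
#'
#' With `N` defined window values and quantile fraction `q`, selects the
#' `k = ceiling(q * N)` highest-scoring windows; the threshold is the k-th
#' largest defined value. Ties at the threshold are broken by genomic order
#' (chrom, start) so exactly `k` windows are returned.
#'
#' @param track A `window_track` with scores in `value`.
#' @param q Upper-tail fraction, `0 < q < 1` (default 0.01, the top 1%).
#' @return List: `threshold`, `k`, `n_defined`, and `selected` (the chosen
#'   windows as a `window_track`, in genomic order).
#' @export
empirical_threshold <- function(track, q = 0.01) {
  if (q <= 0 || q >= 1) stop("q must lie strictly between 0 and 1")
  def <- which(!is.na(track$value))
  N <- length(def)
  if (N < 1L) stop("no defined window values")
  k <- as.integer(ceiling(q * N))
  ord <- def[order(-track$value[def], track$chrom[def], track$start[def])]
  sel_idx <- sort(ord[seq_len(k)])
  sel <- track[sel_idx, , drop = FALSE]
  class(sel) <- c("window_track", "data.frame")
  list(threshold = track$value[ord[k]], k = k, n_defined = N,
       selected = sel)
}

#' Count of top-quantile windows from a distribution size
#'
#' The counting rule of [empirical_threshold()] in isolation:
#' `ceiling(q * N)` windows are selected from `N` defined scores.
#'
#' @param N Number of defined window values.
#' @param q Upper-tail fraction (default 0.01).
#' @return Integer count of selected windows.
#' @export
top_quantile_count <- function(N, q = 0.01) {
  as.integer(ceiling(q * N))
}

#' Annotate selected windows with overlapping genes
#'
#' A window is *annotated* iff it overlaps at least one gene span by >= 1 bp
#' (1-based inclusive intersection; adjacency is not overlap). The gene list
#' is deduplicated by `gene_id` across windows.
#'
#' @param selected A `window_track` of selected windows.
#' @param genes Gene table from [read_genes()].
#' @return List: `annotated_regions` (count of windows with >= 1 gene),
#'   `genes` (unique overlapping gene ids), `hits` (data.frame window row,
#'   gene_id), `per_window` (list of gene ids per window).
#' @export
annotate_regions <- function(selected, genes) {
  nw <- nrow(selected)
  if (nw == 0L || nrow(genes) == 0L) {
    return(list(annotated_regions = 0L, genes = character(),
                hits = data.frame(window = integer(), gene_id = character()),
                per_window = rep(list(character()), nw)))
  }
  per_window <- rep(list(character()), nw)
  hits <- list()
  for (ctg in unique(selected$chrom)) {
    wi <- which(selected$chrom == ctg)
    gi <- which(genes$chrom == ctg)
    if (length(gi) == 0L) next
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(selected$start[wi], selected$end[wi]),
      IRanges::IRanges(genes$start[gi], genes$end[gi]))
    if (length(ov) == 0L) next
    w <- wi[S4Vectors::queryHits(ov)]
    g <- genes$gene_id[gi[S4Vectors::subjectHits(ov)]]
    hits[[length(hits) + 1L]] <- data.frame(window = w, gene_id = g,
                                            stringsAsFactors = FALSE)
  }
  hits <- if (length(hits)) do.call(rbind, hits) else
    data.frame(window = integer(), gene_id = character())
  for (w in unique(hits$window))
    per_window[[w]] <- unique(hits$gene_id[hits$window == w])
  list(annotated_regions = length(unique(hits$window)),
       genes = unique(hits$gene_id), hits = hits, per_window = per_window)
}

#' Build sweep-region records for one scan
#'
#' Joins the selected windows of one method/reference-population run with
#' their overlapping genes into the selected-regions table.
#'
#' @param selected A `window_track` of top-quantile windows.
#' @param genes Gene table from [read_genes()].
#' @param method Scan name (e.g. `"PBS4"`, `"XP-EHH"`).
#' @param reference Reference population label, or `NA` for reference-free
#'   scans.
#' @return Data.frame: `method`, `reference`, `chrom`, `start`, `end`,
#'   `score`, `genes` (comma-separated ids, possibly empty).
#' @export
sweep_regions <- function(selected, genes, method, reference = NA_character_) {
  ann <- annotate_regions(selected, genes)
  data.frame(method = method, reference = reference,
             chrom = selected$chrom, start = selected$start,
             end = selected$end, score = selected$value,
             genes = vapply(ann$per_window, paste, character(1),
                            collapse = ","),
             stringsAsFactors = FALSE)
}

#' Merge per-method sweep regions into a candidate-gene summary
#'
#' One row per gene; one column per method holding that gene's best
#' (maximum) score across its windows and runs, `NA` when the method never
#' hit the gene; reference populations contributing hits are recorded
#' per method.
#'
#' @param region_sets List of data.frames from [sweep_regions()] (possibly
#'   several runs per method).
#' @return Data.frame: `gene_id`, one `<method>` score column per method,
#'   `references` (comma-separated `method:reference` provenance).
#' @export
merge_candidates <- function(region_sets) {
  if (length(region_sets) == 0L)
    return(data.frame(gene_id = character(), stringsAsFactors = FALSE))
  all <- do.call(rbind, region_sets)
  all <- all[nzchar(all$genes), , drop = FALSE]
  if (nrow(all) == 0L)
    return(data.frame(gene_id = character(), stringsAsFactors = FALSE))
  expanded <- do.call(rbind, lapply(seq_len(nrow(all)), function(i) {
    data.frame(gene_id = strsplit(all$genes[i], ",")[[1]],
               method = all$method[i], reference = all$reference[i],
               score = all$score[i], stringsAsFactors = FALSE)
  }))
  methods <- unique(expanded$method)
  genes <- unique(expanded$gene_id)
  out <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
  for (m in methods) {
    out[[m]] <- vapply(genes, function(g) {
      s <- expanded$score[expanded$gene_id == g & expanded$method == m]
      if (length(s) == 0L) NA_real_ else max(s)
    }, numeric(1))
  }
  out$references <- vapply(genes, function(g) {
    e <- expanded[expanded$gene_id == g & !is.na(expanded$reference), ]
    if (nrow(e) == 0L) return("")
    paste(unique(paste0(e$method, ":", e$reference)), collapse = ",")
  }, character(1))
  rownames(out) <- NULL
  out
}
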