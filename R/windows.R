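#' Build sliding windows over contigs
#'
#' Windows are anchored at coordinate 1 on every contig and start at
#' `1, 1 + step, 1 + 2 * step, ...` while the start does not exceed the
#' contig length; the terminal window is truncated at the contig end.
#'
#' @param contig_lengths Named vector: contig name -> length in bp.
#' @param size Window size in bp.
#' @param step Step between window starts in bp (`step <= size`; equal for a
#'   non-overlapping tiling).
#' @return A `window_track` data.frame with columns `chrom`, `start`, `end`,
#'   `n_sites` (NA until sites are assigned), `value` (NA).
#' @export
make_windows <- function(contig_lengths, size, step = size) {
  if (size < 1 || step < 1) stop("size and step must be positive")
  if (step > size) stop("step must not exceed size")
  if (is.null(names(contig_lengths)))
    stop("contig_lengths must be named by contig")
  out <- lapply(names(contig_lengths), function(ctg) {
    len <- contig_lengths[[ctg]]
    starts <- seq(1L, len, by = step)
    data.frame(chrom = ctg, start = as.integer(starts),
               end = as.integer(pmin(starts + size - 1, len)),
               n_sites = NA_integer_, value = NA_real_,
               stringsAsFactors = FALSE)
  })
  w <- do.call(rbind, out)
  class(w) <- c("window_track", "data.frame")
  w
}

#' Assign sorted site positions to windows
#'
#' A site belongs to a window iff `start <= pos <= end`; with overlapping
#' windows a site can belong to several.
#'
#' @param chrom,pos Site coordinates (sorted by position within contig).
#' @param windows A `window_track` (or data.frame with `chrom`, `start`,
#'   `end`).
#' @return List of integer vectors: site indices per window.
#' @export
assign_sites <- function(chrom, pos, windows) {
  lapply(seq_len(nrow(windows)), function(i) {
    which(chrom == windows$chrom[i] &
            pos >= windows$start[i] & pos <= windows$end[i])
  })
}

#' Summarize per-site values into a window track
#'
#' @param chrom,pos Site coordinates.
#' @param value Per-site values (NA allowed).
#' @param windows A `window_track`.
#' @param fun Summary applied to in-window non-NA values (default mean).
#' @param stat Name recorded on the track's `stat` attribute.
#' @return The `window_track` with `n_sites` and `value` filled; windows with
#'   no informative sites keep `value = NA`.
#' @export
window_summarize <- function(chrom, pos, value, windows, fun = mean,
                             stat = "value") {
  idx <- assign_sites(chrom, pos, windows)
  windows$n_sites <- vapply(idx, function(i) sum(!is.na(value[i])),
                            integer(1))
  windows$value <- vapply(idx, function(i) {
    v <- value[i]; v <- v[!is.na(v)]
    if (length(v) == 0L) NA_real_ else fun(v)
  }, numeric(1))
  attr(windows, "stat") <- stat
  windows
}

#' @export
print.window_track <- function(x, ...) {
  stat <- attr(x, "stat")
  cat("window_track", if (!is.null(stat)) paste0("(", stat, ")"), "with",
      nrow(x), "windows;", sum(!is.na(x$value)), "defined values\n")
  print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}

#' Read/write the shared window TSV interchange format
#'
#' Columns: `chrom`, `start`, `end`, `n_sites`, `value`; undefined values are
#' written as `NA`. Externally computed per-window score tables (e.g. a
#' composite-likelihood scan) written in this layout can be re-ingested and
#' thresholded/annotated identically to native tracks.
#'
#' @param track A `window_track`.
#' @param path File path.
#' @return `read_window_track`: a `window_track`; `write_window_track`:
#'   `path`, invisibly.
#' @export
write_window_track <- function(track, path) {
  write.table(as.data.frame(track)[, c("chrom", "start", "end",
                                       "n_sites", "value")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_window_track
#' @export
read_window_track <- function(path) {
  w <- read.table(path, header = TRUE, sep = "\t",
                  stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "value")
  if (!all(need %in% names(w)))
    stop("window TSV must have columns chrom, start, end, value")
  if (is.null(w$n_sites)) w$n_sites <- NA_integer_
  w <- w[, c("chrom", "start", "end", "n_sites", "value")]
  w$chrom <- as.character(w$chrom)
  class(w) <- c("window_track", "data.frame")
  w
}
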