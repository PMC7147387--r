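# Fixed sliding-window grid: 150 kb windows advancing by 75 kb by default,
# so consecutive windows overlap by half. Coordinates are 1-based inclusive
# internally; BED export is 0-based half-open.

#' Build the sliding-window grid
#'
#' Windows start at 1, 1+step, 1+2*step, ... on every chromosome; only
#' full-length windows (end within the chromosome) are emitted, ordered by
#' chromosome then start. A chromosome shorter than one window contributes
#' no windows.
#'
#' @param chrom_lengths named vector of chromosome lengths in bp.
#' @param size window size in bp (default 150000).
#' @param step distance between consecutive window starts (default 75000;
#'   must satisfy 0 < step <= size).
#' @return data.table (chrom, start, end, widx) with grid parameters and
#'   the chromosome-length table stored as attributes.
#' @export
make_windows <- function(chrom_lengths, size = 150000L, step = 75000L) {
  if (is.null(names(chrom_lengths)))
    stop("chrom_lengths must be named")
  size <- as.integer(size); step <- as.integer(step)
  if (step <= 0L || step > size)
    stop("require 0 < step <= size (got step = ", step, ", size = ", size, ")")
  win <- rbindlist(lapply(names(chrom_lengths), function(ch) {
    L <- as.numeric(chrom_lengths[[ch]])
    if (L < size) return(NULL)
    nwin <- floor((L - size) / step) + 1
    starts <- 1L + (seq_len(nwin) - 1L) * step
    data.table(chrom = ch, start = starts, end = starts + size - 1L)
  }))
  if (is.null(win) || nrow(win) == 0L)
    win <- data.table(chrom = character(), start = integer(), end = integer())
  win[, widx := .I]
  setattr(win, "window_size", size)
  setattr(win, "window_step", step)
  setattr(win, "chrom_lengths", chrom_lengths)
  win[]
}

#' Assign sites to windows
#'
#' A site at position p belongs to window [s, e] iff s <= p <= e; with the
#' default half-overlapping grid an interior site falls in exactly two
#' windows.
#'
#' @param windows grid from [make_windows()].
#' @param sites data.table with chrom and pos columns (coordinate-sorted),
#'   or a `sweep_sites` / `group_counts` object.
#' @return data.table (widx, site_idx), one row per window/site incidence,
#'   ordered by widx. `site_idx` indexes rows of `sites`.
#' @export
assign_sites <- function(windows, sites) {
  if (inherits(sites, "sweep_sites")) sites <- sites$meta
  cl <- attr(windows, "chrom_lengths")
  if (!is.null(cl)) {
    bad <- setdiff(unique(sites$chrom), names(cl))
    if (length(bad))
      stop("site(s) on chromosome(s) absent from the length table: ",
           paste(bad, collapse = ", "))
  }
  if (nrow(windows) == 0L || nrow(sites) == 0L)
    return(data.table(widx = integer(), site_idx = integer()))
  wgr <- GenomicRanges::GRanges(windows$chrom,
                                IRanges::IRanges(windows$start, windows$end))
  sgr <- GenomicRanges::GRanges(sites$chrom,
                                IRanges::IRanges(sites$pos, width = 1L))
  hits <- GenomicRanges::findOverlaps(wgr, sgr)
  out <- data.table(widx = windows$widx[S4Vectors::queryHits(hits)],
                    site_idx = S4Vectors::subjectHits(hits))
  setorder(out, widx, site_idx)
  out[]
}

#' Window retention mask from per-group SNP counts
#'
#' A window is retained for a group iff it holds at least `min_snps`
#' informative SNPs in that group; downstream contrast statistics require
#' retention in both groups.
#'
#' @param snp_counts matrix (windows x groups) of informative SNP counts.
#' @param min_snps retention threshold (default 20; windows with fewer are
#'   discarded).
#' @return logical matrix of the same shape.
#' @export
retain_windows <- function(snp_counts, min_snps = 20L) {
  stopifnot(is.matrix(snp_counts), min_snps >= 0)
  snp_counts >= min_snps
}
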