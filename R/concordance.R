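# Cross-dataset validation: align two scans on the shared window grid,
# test whether one dataset's candidate windows show shifted homozygosity in
# the other, intersect significant window sets into shared regions, and
# correlate the dZHp profiles.

#' Align two per-window tables on the shared grid
#'
#' Inner join on (chrom, start, end). Both tables must carry identical grid
#' parameters (window_size / window_step attributes, as produced by
#' [scan_sweeps()] or [read_scan_table()]).
#'
#' @param table_a,table_b window tables.
#' @param suffixes column-name suffixes for the two datasets.
#' @return the aligned data.table; attributes `n_a_only` / `n_b_only` count
#'   unmatched windows. Empty joins are allowed with a warning.
#' @export
match_windows <- function(table_a, table_b, suffixes = c("_a", "_b")) {
  ga <- c(attr(table_a, "window_size"), attr(table_a, "window_step"))
  gb <- c(attr(table_b, "window_size"), attr(table_b, "window_step"))
  if (!is.null(ga) && !is.null(gb) && !identical(as.integer(ga),
                                                 as.integer(gb)))
    stop("window grids differ between datasets: (",
         paste(ga, collapse = "/"), ") vs (", paste(gb, collapse = "/"), ")")
  a <- as.data.table(table_a); b <- as.data.table(table_b)
  key <- c("chrom", "start", "end")
  m <- merge(a, b, by = key, suffixes = suffixes, sort = TRUE)
  if (nrow(m) == 0L)
    warning("no windows in common between the two datasets", call. = FALSE)
  setattr(m, "n_a_only", nrow(a) - nrow(m))
  setattr(m, "n_b_only", nrow(b) - nrow(m))
  setattr(m, "window_size", if (!is.null(ga)) as.integer(ga[1]))
  setattr(m, "window_step", if (!is.null(ga)) as.integer(ga[2]))
  m[]
}

#' One-sided rank-shift (Mann-Whitney) test of candidate windows
#'
#' Tests whether the statistic is larger over candidate windows than over
#' the remaining (background) windows, e.g. whether windows flagged in
#' dataset A are more homozygous (larger -ZHp) in dataset B. Uses exact
#' enumeration of all choose(n, n1) candidate/background rank assignments
#' when both group sizes are <= `exact_max` (ties handled by midranks),
#' and the normal approximation with tie correction and continuity
#' correction otherwise. A fully tied input is degenerate: p = 0.5 with a
#' warning.
#'
#' @param stat numeric statistic per matched window (larger = more extreme
#'   in the direction of the hypothesis; pass -ZHp to test increased
#'   homozygosity).
#' @param candidate logical vector flagging candidate windows.
#' @param exact_max exact-enumeration size limit per group (default 10).
#' @return list: p (one-sided, candidates greater), statistic (candidate
#'   rank sum W), n_candidate, n_background, method ("exact" or "normal"),
#'   degenerate flag.
#' @export
rank_shift_test <- function(stat, candidate, exact_max = 10L) {
  stopifnot(length(stat) == length(candidate), is.logical(candidate))
  keep <- !is.na(stat)
  stat <- stat[keep]; candidate <- candidate[keep]
  n1 <- sum(candidate); n2 <- sum(!candidate); n <- n1 + n2
  if (n1 == 0L) stop("empty candidate set")
  if (n2 == 0L) stop("empty background set")
  r <- rank(stat)
  W <- sum(r[candidate])
  if (stats::var(stat) == 0) {
    warning("all values tied between candidates and background; ",
            "rank-shift test is degenerate", call. = FALSE)
    return(list(p = 0.5, statistic = W, n_candidate = n1,
                n_background = n2, method = "degenerate",
                degenerate = TRUE))
  }
  if (n1 <= exact_max && n2 <= exact_max) {
    sets <- combn(n, n1)
    Wperm <- colSums(matrix(r[sets], nrow = n1))
    p <- mean(Wperm >= W - 1e-9)
    method <- "exact"
  } else {
    mu <- n1 * (n + 1) / 2
    ties <- table(r)
    sig2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    p <- pnorm((W - mu - 0.5) / sqrt(sig2), lower.tail = FALSE)
    method <- "normal"
  }
  list(p = p, statistic = W, n_candidate = n1, n_background = n2,
       method = method, degenerate = FALSE)
}

#' Intersect significant windows of two datasets into shared regions
#'
#' Keeps windows significant in the same direction in both datasets and
#' merges overlapping or book-ended grid windows into maximal regions.
#' Symmetric in its two arguments.
#'
#' @param calls_a,calls_b data.tables of significant windows (chrom, start,
#'   end, direction), e.g. `outlier_windows(..., merge = FALSE)` output.
#' @return data.table of shared regions (chrom, start, end, direction,
#'   n_windows). Attribute "n_shared_windows" gives the pre-merge shared
#'   window count.
#' @export
intersect_significant <- function(calls_a, calls_b) {
  key <- c("chrom", "start", "end", "direction")
  a <- unique(as.data.table(calls_a)[, ..key])
  b <- unique(as.data.table(calls_b)[, ..key])
  shared <- merge(a, b, by = key, sort = TRUE)
  if (nrow(shared) == 0L) {
    out <- data.table(chrom = character(), start = integer(),
                      end = integer(), direction = character(),
                      n_windows = integer())
    setattr(out, "n_shared_windows", 0L)
    return(out[])
  }
  pieces <- lapply(split(shared, by = "direction"), function(sub) {
    gr <- GenomicRanges::GRanges(sub$chrom,
                                 IRanges::IRanges(sub$start, sub$end))
    red <- GenomicRanges::reduce(gr, min.gapwidth = 1L)
    hit <- GenomicRanges::findOverlaps(red, gr)
    cnt <- tabulate(S4Vectors::queryHits(hit), length(red))
    data.table(chrom = as.character(GenomicRanges::seqnames(red)),
               start = GenomicRanges::start(red),
               end = GenomicRanges::end(red),
               direction = sub$direction[1L], n_windows = cnt)
  })
  out <- rbindlist(pieces)
  setorder(out, chrom, start)
  setattr(out, "n_shared_windows", nrow(shared))
  out[]
}

#' Correlation of dZHp profiles between datasets
#'
#' Pearson correlation over matched windows, with r^2 and the usual t-test
#' p-value.
#'
#' @param delta_a,delta_b aligned dZHp vectors (NA pairs dropped).
#' @return list: r, r2, p, n.
#' @export
delta_correlation <- function(delta_a, delta_b) {
  stopifnot(length(delta_a) == length(delta_b))
  keep <- !is.na(delta_a) & !is.na(delta_b)
  x <- delta_a[keep]; y <- delta_b[keep]
  if (length(x) < 3L) stop("need >= 3 aligned windows")
  if (sd(x) == 0 || sd(y) == 0)
    stop("zero variance in a dZHp vector; correlation undefined")
  ct <- cor.test(x, y)
  list(r = unname(ct$estimate), r2 = unname(ct$estimate)^2,
       p = ct$p.value, n = length(x))
}
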