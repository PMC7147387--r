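# Core sweep statistics: pooled heterozygosity Hp per window, genome-wide
# Z-transform, the wild-minus-farmed contrast dZHp, the Weir-Cockerham
# theta estimator aggregated per window, and outlier calling with
# Bonferroni correction.

#' Pooled heterozygosity of one window
#'
#' Hp = 2 A B / (A + B)^2 where A and B are the sums of the group-wise
#' major and minor allele read counts over all SNPs in the window. The sums
#' are taken before the ratio (this is not a mean of per-site values).
#' Hp is bounded in [0, 0.5], reaching 0.5 only when A = B, and is
#' invariant to scaling all counts by a positive constant.
#'
#' @param n_maj,n_min per-site major/minor read counts for the window's
#'   SNPs (equal length).
#' @return Hp, or NA (with a warning) when the window carries no reads.
#' @export
window_hp <- function(n_maj, n_min) {
  stopifnot(length(n_maj) == length(n_min))
  A <- sum(n_maj); B <- sum(n_min)
  if (A + B == 0) {
    warning("window has no reads; Hp undefined", call. = FALSE)
    return(NA_real_)
  }
  2 * A * B / (A + B)^2
}

#' Genome-wide Z-transform
#'
#' Centers and scales by the sample standard deviation (denominator n - 1)
#' over the supplied values, which should be the Hp of all retained windows
#' of one group: ZHp = (Hp - mean) / sd.
#'
#' @param values numeric vector, >= 2 values, not all equal.
#' @return z-scores with mean 0 and sample sd 1.
#' @export
z_transform <- function(values) {
  if (length(values) < 2L) stop("need >= 2 values to standardize")
  s <- sd(values)
  if (!is.finite(s) || s == 0) stop("degenerate distribution: sd is 0")
  (values - mean(values)) / s
}

#' Directional heterozygosity contrast
#'
#' dZHp = ZHp_wild - ZHp_farmed per window. Positive values mark windows
#' where the farmed group lost heterozygosity relative to the wild group
#' (the domestication signal); the statistic is antisymmetric under group
#' swap.
#'
#' @param zhp_wild,zhp_farmed equal-length numeric vectors on the same
#'   window set; if both are named, the names must match.
#' @return dZHp per window.
#' @export
delta_zhp <- function(zhp_wild, zhp_farmed) {
  if (length(zhp_wild) != length(zhp_farmed))
    stop("mismatched window sets: ", length(zhp_wild), " vs ",
         length(zhp_farmed), " windows")
  if (!is.null(names(zhp_wild)) && !is.null(names(zhp_farmed)) &&
      !identical(names(zhp_wild), names(zhp_farmed)))
    stop("mismatched window sets: names differ")
  zhp_wild - zhp_farmed
}

#' Per-site Weir-Cockerham theta for two populations
#'
#' Allele-count (haploid-sample) form of the Weir-Cockerham variance
#' decomposition for r = 2 populations, vectorized over sites:
#' pbar = (n1 p1 + n2 p2)/(n1 + n2);
#' MSP = sum n_i (p_i - pbar)^2 / (r - 1);
#' MSG = sum n_i p_i (1 - p_i) / sum (n_i - 1);
#' n_c = (sum n_i - sum n_i^2 / sum n_i) / (r - 1);
#' theta = (MSP - MSG) / (MSP + (n_c - 1) MSG).
#' Numerator and denominator are retained so windows can aggregate by
#' ratio of sums. Monomorphic sites (MSP = MSG = 0) and sites with fewer
#' than 2 allele observations in a population are flagged undefined.
#' Negative theta values are reported as computed, not clamped.
#'
#' @param p1,p2 alternate-allele frequencies per population.
#' @param n1,n2 allele sample sizes (reads for pool-seq; 2 x called
#'   diploids for genotype data).
#' @return data.table (p1, p2, n1, n2, msp, msg, nc, num, den, theta,
#'   defined), one row per site.
#' @export
wc_fst_site <- function(p1, p2, n1, n2) {
  k <- max(length(p1), length(p2), length(n1), length(n2))
  p1 <- rep_len(as.numeric(p1), k); p2 <- rep_len(as.numeric(p2), k)
  n1 <- rep_len(as.numeric(n1), k); n2 <- rep_len(as.numeric(n2), k)
  ntot <- n1 + n2
  valid <- n1 >= 1 & n2 >= 1 & ntot > 2
  pbar <- (n1 * p1 + n2 * p2) / ntot
  msp <- n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2           # / (r - 1) = 1
  msg <- (n1 * p1 * (1 - p1) + n2 * p2 * (1 - p2)) / (ntot - 2)
  nc <- ntot - (n1^2 + n2^2) / ntot                         # / (r - 1) = 1
  num <- msp - msg
  den <- msp + (nc - 1) * msg
  defined <- valid & (msp > 0 | msg > 0) & den > 0
  theta <- ifelse(defined, num / den, NA_real_)
  bad <- !valid | (msp == 0 & msg == 0)
  num[bad] <- 0; den[bad] <- 0
  msp[!valid] <- 0; msg[!valid] <- 0
  data.table(p1 = p1, p2 = p2, n1 = n1, n2 = n2, msp = msp, msg = msg,
             nc = nc, num = num, den = den, theta = theta,
             defined = defined)
}

#' Window-level Weir-Cockerham FST
#'
#' Ratio of sums over the window's defined sites: sum of per-site theta
#' numerators divided by sum of denominators (the weighted estimator used
#' by windowed FST tools), not a mean of per-site ratios.
#'
#' @param num,den per-site theta components from [wc_fst_site()].
#' @param defined logical per-site definedness flag.
#' @return window FST, or NA when no site is defined.
#' @export
wc_fst_window <- function(num, den, defined = den > 0) {
  D <- sum(den[defined])
  if (!length(den) || D == 0) return(NA_real_)
  sum(num[defined]) / D
}

#' Run the windowed sweep scan on per-group allele counts
#'
#' Aggregates per-site major/minor counts into the window grid, applies the
#' per-group minimum-SNP retention rule, computes Hp and its genome-wide
#' Z-transform per group, the contrast dZHp = ZHp_wild - ZHp_farmed on
#' windows retained in both groups, windowed Weir-Cockerham FST between the
#' contrast groups, and one-sided normal-tail p-values with Bonferroni
#' adjustment over the tested windows.
#'
#' @param counts a [group_counts()] table.
#' @param windows grid from [make_windows()].
#' @param contrast length-2 character: c(wild-like, farmed-like) group
#'   names; dZHp = ZHp of the first minus ZHp of the second. Defaults to
#'   c("wild", "farmed") when those labels exist, else the first two
#'   groups.
#' @param min_snps per-group window retention threshold (default 20).
#' @param fst_n_cap optional named vector capping each group's allele
#'   sample size in the FST estimator (e.g. 2 x pooled diploids) to guard
#'   against pseudo-replication from read counts; NULL uses read counts
#'   as-is.
#' @param restandardize if TRUE, dZHp is re-standardized (Z-transformed)
#'   before tail p-values are computed; the default treats dZHp as
#'   standard normal, which is conservative in the upper tail because the
#'   two groups' ZHp are positively correlated.
#' @return data.table with one row per window: chrom, start, end, widx,
#'   per-group `n_snps_`, `hp_`, `zhp_` columns, delta_zhp, fst, p_up,
#'   p_dn, p_adj_up, p_adj_dn. Attributes: window_size, window_step,
#'   min_snps, groups, contrast, n_tested.
#' @export
scan_sweeps <- function(counts, windows, contrast = NULL, min_snps = 20L,
                        fst_n_cap = NULL, restandardize = FALSE) {
  groups <- attr(counts, "groups")
  if (is.null(groups)) stop("counts must come from group_counts()")
  if (is.null(contrast)) {
    contrast <- if (all(c("wild", "farmed") %in% groups))
      c("wild", "farmed") else groups[1:2]
  }
  stopifnot(length(contrast) == 2L, all(contrast %in% groups))

  map <- assign_sites(windows, counts)
  stats <- windows[, .(chrom, start, end, widx)]
  for (g in groups) {
    inf <- counts[[paste0("informative_", g)]][map$site_idx]
    dt <- data.table(widx = map$widx, inf = inf,
                     nmaj = counts[[paste0("nmaj_", g)]][map$site_idx],
                     nmin = counts[[paste0("nmin_", g)]][map$site_idx])
    agg <- dt[, .(n = sum(inf), A = sum(nmaj), B = sum(nmin)), by = widx]
    i <- match(stats$widx, agg$widx)
    n <- ifelse(is.na(i), 0L, agg$n[i])
    A <- ifelse(is.na(i), 0, agg$A[i])
    B <- ifelse(is.na(i), 0, agg$B[i])
    retained <- n >= min_snps & (A + B) > 0
    hp <- ifelse(retained, 2 * A * B / (A + B)^2, NA_real_)
    zhp <- rep(NA_real_, nrow(stats))
    if (sum(retained) >= 2L && sd(hp[retained]) > 0)
      zhp[retained] <- z_transform(hp[retained])
    set(stats, j = paste0("n_snps_", g), value = as.integer(n))
    set(stats, j = paste0("hp_", g), value = hp)
    set(stats, j = paste0("zhp_", g), value = zhp)
  }
  zw <- stats[[paste0("zhp_", contrast[1])]]
  zf <- stats[[paste0("zhp_", contrast[2])]]
  stats[, delta_zhp := zw - zf]

  # windowed Weir-Cockerham FST between the contrast groups
  r1 <- counts[[paste0("ref_", contrast[1])]]
  a1 <- counts[[paste0("alt_", contrast[1])]]
  r2 <- counts[[paste0("ref_", contrast[2])]]
  a2 <- counts[[paste0("alt_", contrast[2])]]
  n1 <- r1 + a1; n2 <- r2 + a2
  if (!is.null(fst_n_cap)) {
    n1 <- pmin(n1, fst_n_cap[[contrast[1]]])
    n2 <- pmin(n2, fst_n_cap[[contrast[2]]])
  }
  ok <- n1 > 0 & n2 > 0
  p1 <- ifelse(ok, a1 / pmax(r1 + a1, 1), NA_real_)
  p2 <- ifelse(ok, a2 / pmax(r2 + a2, 1), NA_real_)
  fc <- wc_fst_site(ifelse(ok, p1, 0), ifelse(ok, p2, 0),
                    ifelse(ok, n1, 0), ifelse(ok, n2, 0))
  fc[!ok, `:=`(num = 0, den = 0, defined = FALSE)]
  fdt <- data.table(widx = map$widx, num = fc$num[map$site_idx],
                    den = fc$den[map$site_idx],
                    def = fc$defined[map$site_idx])
  fagg <- fdt[, .(fst = wc_fst_window(num, den, def)), by = widx]
  stats[, fst := fagg$fst[match(widx, fagg$widx)]]

  score <- stats$delta_zhp
  n_tested <- sum(!is.na(score))
  if (restandardize && n_tested >= 2L)
    score[!is.na(score)] <- z_transform(score[!is.na(score)])
  stats[, p_up := pnorm(score, lower.tail = FALSE)]
  stats[, p_dn := pnorm(score)]
  stats[, p_adj_up := pmin(1, n_tested * p_up)]
  stats[, p_adj_dn := pmin(1, n_tested * p_dn)]

  setattr(stats, "window_size", attr(windows, "window_size"))
  setattr(stats, "window_step", attr(windows, "window_step"))
  setattr(stats, "min_snps", as.integer(min_snps))
  setattr(stats, "groups", groups)
  setattr(stats, "contrast", contrast)
  setattr(stats, "n_tested", n_tested)
  stats[]
}

#' Call outlier windows and merge them into sweep regions
#'
#' Flags windows whose score exceeds a fixed threshold (`mode = "zthr"`) or
#' whose Bonferroni-adjusted one-sided normal p-value falls below `alpha`
#' (`mode = "alpha"`, p_adj = min(1, N p) with N the number of scored
#' windows), in the requested tail(s). Runs of overlapping significant
#' windows on one chromosome, same direction, are merged into maximal
#' regions.
#'
#' @param stats a window table from [scan_sweeps()] (or any table with
#'   chrom, start, end and the score column).
#' @param score_col column holding the score (default "delta_zhp").
#' @param mode "zthr" (fixed threshold) or "alpha" (Bonferroni).
#' @param zthr threshold for mode "zthr" (default 3).
#' @param alpha family-wise error rate for mode "alpha", in (0, 1).
#' @param direction "both", "upper" or "lower" tail. For dZHp the upper
#'   tail is heterozygosity loss in the farmed (second contrast) group.
#' @param merge merge overlapping significant windows into regions
#'   (default TRUE); FALSE returns one row per significant window.
#' @return data.table of calls: chrom, start, end, direction, n_windows,
#'   peak_score, min_p_adj. Attribute "n_significant_windows" holds the
#'   pre-merge window count.
#' @export
outlier_windows <- function(stats, score_col = "delta_zhp",
                            mode = c("zthr", "alpha"), zthr = 3,
                            alpha = 0.05,
                            direction = c("both", "upper", "lower"),
                            merge = TRUE) {
  mode <- match.arg(mode)
  direction <- match.arg(direction)
  if (mode == "alpha" && (alpha <= 0 || alpha >= 1))
    stop("alpha must be in (0, 1)")
  score <- stats[[score_col]]
  if (is.null(score)) stop("no column '", score_col, "' in stats")
  n_tested <- sum(!is.na(score))
  p_up <- pmin(1, n_tested * pnorm(score, lower.tail = FALSE))
  p_dn <- pmin(1, n_tested * pnorm(score))
  sig_up <- !is.na(score) &
    (if (mode == "zthr") score > zthr else p_up < alpha)
  sig_dn <- !is.na(score) &
    (if (mode == "zthr") score < -zthr else p_dn < alpha)
  if (direction == "upper") sig_dn[] <- FALSE
  if (direction == "lower") sig_up[] <- FALSE

  contrast <- attr(stats, "contrast")
  lab <- if (!is.null(contrast))
    c(upper = paste0(contrast[2], "_loss"),
      lower = paste0(contrast[1], "_loss"))
  else c(upper = "upper", lower = "lower")

  one_tail <- function(sig, tail) {
    if (!any(sig)) return(NULL)
    sub <- data.table(chrom = stats$chrom[sig], start = stats$start[sig],
                      end = stats$end[sig], score = score[sig],
                      p_adj = if (tail == "upper") p_up[sig] else p_dn[sig])
    if (!merge) {
      sub[, `:=`(direction = lab[[tail]], n_windows = 1L)]
      setnames(sub, c("score", "p_adj"), c("peak_score", "min_p_adj"))
      return(sub[, .(chrom, start, end, direction, n_windows,
                     peak_score, min_p_adj)])
    }
    gr <- GenomicRanges::GRanges(sub$chrom,
                                 IRanges::IRanges(sub$start, sub$end))
    red <- GenomicRanges::reduce(gr, min.gapwidth = 0L)
    hit <- GenomicRanges::findOverlaps(red, gr)
    sub[, run_id := NA_integer_]
    sub$run_id[S4Vectors::subjectHits(hit)] <- S4Vectors::queryHits(hit)
    out <- sub[, .(chrom = chrom[1L], start = min(start), end = max(end),
                   n_windows = .N,
                   peak_score = score[which.max(abs(score))],
                   min_p_adj = min(p_adj)), by = run_id]
    out[, direction := lab[[tail]]]
    out[, run_id := NULL]
    out[, .(chrom, start, end, direction, n_windows, peak_score, min_p_adj)]
  }
  calls <- rbindlist(list(one_tail(sig_up, "upper"),
                          one_tail(sig_dn, "lower")))
  if (is.null(calls) || nrow(calls) == 0L)
    calls <- data.table(chrom = character(), start = integer(),
                        end = integer(), direction = character(),
                        n_windows = integer(), peak_score = numeric(),
                        min_p_adj = numeric())
  setorder(calls, chrom, start)
  setattr(calls, "n_significant_windows",
          c(upper = sum(sig_up), lower = sum(sig_dn)))
  calls[]
}
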