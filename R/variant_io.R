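# VCF input, site filtering and per-group major/minor read counts.
#
# Sites are held as a `sweep_sites` object: a site metadata table plus
# aligned per-sample matrices of allelic depths (ref/alt), genotype dosage
# (individual mode) and callability. All downstream statistics consume this
# container, whether it came from a VCF or straight from the simulator.

#' Assign VCF samples to population groups
#'
#' @param sample_id character vector of sample names (must match the VCF).
#' @param group group label per sample.
#' @param mode sequencing mode per group: "pooled" (allele depths carry the
#'   information) or "individual" (genotypes; AD used when present).
#'   All samples of one group must share a mode.
#' @return a `group_assignment` data.table (sample_id, group, mode).
#' @export
group_assignment <- function(sample_id, group, mode = "pooled") {
  dt <- data.table(sample_id = as.character(sample_id),
                   group = as.character(group),
                   mode = rep_len(as.character(mode), length(sample_id)))
  if (anyDuplicated(dt$sample_id))
    stop("each sample must be assigned exactly once")
  if (!all(dt$mode %in% c("pooled", "individual")))
    stop("mode must be 'pooled' or 'individual'")
  bad <- dt[, uniqueN(mode), by = group][V1 > 1L, group]
  if (length(bad))
    stop("mixed modes within group(s): ", paste(bad, collapse = ", "))
  setattr(dt, "class", c("group_assignment", class(dt)))
  dt[]
}

#' Read a sample-to-group assignment TSV
#'
#' Expects 2-3 tab-separated columns (sample, group, mode); `mode` defaults
#' to "pooled" when absent. A header line is detected by the literal first
#' field "sample".
#'
#' @param path TSV path.
#' @return a [group_assignment()] object.
#' @export
read_group_file <- function(path) {
  dt <- fread(path, header = "auto", sep = "\t")
  if (ncol(dt) < 2L) stop("group file needs >= 2 columns (sample, group)")
  group_assignment(dt[[1]], dt[[2]],
                   if (ncol(dt) >= 3L) dt[[3]] else "pooled")
}

# internal constructor shared by read_sites() and sim_as_sites()
new_sweep_sites <- function(meta, ad_ref, ad_alt, gt, callable, assignment,
                            source, filtered = FALSE, drop_tally = NULL) {
  structure(list(meta = meta, ad_ref = ad_ref, ad_alt = ad_alt, gt = gt,
                 callable = callable, assignment = assignment,
                 source = source, filtered = filtered,
                 drop_tally = drop_tally),
            class = "sweep_sites")
}

#' @export
print.sweep_sites <- function(x, ...) {
  cat(sprintf("sweep_sites: %d sites, %d samples in %d group(s) [%s]%s\n",
              nrow(x$meta), nrow(x$assignment),
              uniqueN(x$assignment$group), x$source,
              if (x$filtered) ", filtered" else ""))
  invisible(x)
}

#' Number of sites in a `sweep_sites` object
#' @param x a `sweep_sites` object.
#' @return integer site count.
#' @export
n_sites <- function(x) nrow(x$meta)

# parse "0/1"-style GT strings into alt-allele dosage; anything with a
# missing or non-biallelic allele becomes NA
.gt_dosage <- function(gt) {
  out <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  known <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L,
             "0|0" = 0L, "0|1" = 1L, "1|0" = 1L, "1|1" = 2L,
             "0" = 0L, "1" = 1L)
  m <- known[gt]
  out[] <- m
  out
}

# extract (ref, alt1) depth matrices from VariantAnnotation's AD geno,
# which may be a list-matrix (Number=R) or a 3d array
.ad_matrices <- function(ad, n, samples) {
  ref <- alt <- matrix(NA_integer_, n, length(samples),
                       dimnames = list(NULL, samples))
  if (is.null(ad)) return(NULL)
  if (is.array(ad) && length(dim(ad)) == 3L) {
    ref[] <- ad[, , 1L]
    alt[] <- ad[, , 2L]
  } else {
    take <- function(k) {
      v <- vapply(ad, function(x)
        if (length(x) >= k && !is.null(x)) as.integer(x[k]) else NA_integer_,
        integer(1))
      matrix(v, n, length(samples))
    }
    ref[] <- take(1L)
    alt[] <- take(2L)
  }
  list(ref = ref, alt = alt)
}

#' Read variant sites from a multi-sample VCF
#'
#' Loads all records (filtering is a separate, explicit step) and attaches
#' the group assignment. Pooled-mode groups require the AD FORMAT field;
#' individual-mode groups require GT (AD is used for read counts when
#' present). Sites are returned in coordinate order.
#'
#' @param path VCF path (plain or bgzipped).
#' @param assignment a [group_assignment()]; every VCF sample must appear.
#' @return a `sweep_sites` object.
#' @export
read_sites <- function(path, assignment) {
  stopifnot(inherits(assignment, "group_assignment"))
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  vcf_samples <- colnames(vcf)
  missing_asn <- setdiff(vcf_samples, assignment$sample_id)
  if (length(missing_asn))
    stop("VCF sample(s) not in the group assignment: ",
         paste(missing_asn, collapse = ", "))
  missing_vcf <- setdiff(assignment$sample_id, vcf_samples)
  if (length(missing_vcf))
    stop("assigned sample(s) absent from the VCF: ",
         paste(missing_vcf, collapse = ", "))
  # order matrices by the assignment's sample order
  samples <- assignment$sample_id
  n <- length(vcf)

  alt_list <- VariantAnnotation::alt(vcf)
  n_alt <- S4Vectors::elementNROWS(alt_list)
  ref_chr <- as.character(VariantAnnotation::ref(vcf))
  alt1 <- rep(NA_character_, n)
  if (any(n_alt >= 1L)) {
    alt_flat <- as.character(unlist(alt_list))
    first_of_each <- cumsum(n_alt) - n_alt + 1L
    alt1[n_alt >= 1L] <- alt_flat[first_of_each[n_alt >= 1L]]
  }
  biallelic_snp <- n_alt == 1L & nchar(ref_chr) == 1L &
    !is.na(alt1) & nchar(alt1) == 1L &
    ref_chr %in% c("A", "C", "G", "T") & alt1 %in% c("A", "C", "G", "T")

  inf <- VariantAnnotation::info(vcf)
  mq <- if ("MQ" %in% names(inf)) as.numeric(inf$MQ) else rep(NA_real_, n)
  dp_info <- if ("DP" %in% names(inf)) as.integer(inf$DP)
             else rep(NA_integer_, n)

  gen <- VariantAnnotation::geno(vcf)
  ad <- if ("AD" %in% names(gen)) .ad_matrices(gen$AD[, vcf_samples, drop = FALSE],
                                               n, vcf_samples)
        else NULL
  gt_raw <- if ("GT" %in% names(gen)) gen$GT[, vcf_samples, drop = FALSE]
            else NULL

  modes <- assignment[match(vcf_samples, sample_id), mode]
  if (is.null(ad) && any(modes == "pooled")) {
    s <- vcf_samples[modes == "pooled"][1]
    stop("pooled-mode sample '", s, "' requires the AD FORMAT field, ",
         "which is absent from ", path)
  }
  if (is.null(gt_raw) && is.null(ad) && any(modes == "individual")) {
    s <- vcf_samples[modes == "individual"][1]
    stop("individual-mode sample '", s, "' requires the GT (or AD) FORMAT ",
         "field, which is absent from ", path)
  }

  # reorder to the assignment order
  ord <- match(samples, vcf_samples)
  ad_ref <- ad_alt <- matrix(0L, n, length(samples),
                             dimnames = list(NULL, samples))
  if (!is.null(ad)) {
    ad_ref[] <- ad$ref[, ord, drop = FALSE]
    ad_alt[] <- ad$alt[, ord, drop = FALSE]
    ad_ref[is.na(ad_ref)] <- 0L
    ad_alt[is.na(ad_alt)] <- 0L
  }
  gt <- if (!is.null(gt_raw))
    .gt_dosage(gt_raw[, ord, drop = FALSE]) else
    matrix(NA_integer_, n, length(samples))
  dimnames(gt) <- list(NULL, samples)

  mode_by_sample <- assignment$mode
  callable <- matrix(FALSE, n, length(samples),
                     dimnames = list(NULL, samples))
  has_reads <- (ad_ref + ad_alt) > 0L
  for (j in seq_along(samples)) {
    callable[, j] <- if (mode_by_sample[j] == "individual" && !is.null(gt_raw))
      !is.na(gt[, j]) else has_reads[, j]
  }

  dp <- dp_info
  if (anyNA(dp)) {
    dp_sum <- as.integer(rowSums(ad_ref) + rowSums(ad_alt))
    dp[is.na(dp)] <- dp_sum[is.na(dp)]
  }
  meta <- data.table(chrom = as.character(GenomicRanges::seqnames(rr)),
                     pos = GenomicRanges::start(rr),
                     ref = ref_chr, alt = alt1,
                     biallelic_snp = biallelic_snp, mq = mq, dp = dp)
  o <- meta[, order(chrom, pos)]
  new_sweep_sites(meta[o], ad_ref[o, , drop = FALSE],
                  ad_alt[o, , drop = FALSE], gt[o, , drop = FALSE],
                  callable[o, , drop = FALSE], assignment, source = path)
}

#' Apply the site-quality filters
#'
#' Retains biallelic SNPs with site mapping quality >= `mq_min`, site read
#' depth >= `dp_min`, and a callable fraction strictly greater than
#' `call_rate_min` across all assigned samples. The drop tally attributes
#' each removed site to its first failing rule, checked in the order
#' allele class, mapping quality, depth, call rate.
#'
#' @param x a `sweep_sites` object.
#' @param mq_min minimum site mapping quality (sites with no MQ annotation
#'   pass this rule; a warning is issued once).
#' @param dp_min minimum aggregate site depth.
#' @param call_rate_min callable-sample fraction that must be exceeded
#'   (strict inequality: exactly `call_rate_min` is dropped).
#' @return filtered `sweep_sites`; the per-rule drop tally is available via
#'   [drop_tally()]. Idempotent.
#' @export
filter_sites <- function(x, mq_min = 50, dp_min = 5, call_rate_min = 0.90) {
  stopifnot(inherits(x, "sweep_sites"), is.finite(mq_min), is.finite(dp_min),
            is.finite(call_rate_min))
  meta <- x$meta
  if (anyNA(meta$mq))
    warning("site MQ annotation missing for ", sum(is.na(meta$mq)),
            " site(s); these pass the mapping-quality rule", call. = FALSE)
  ok_class <- meta$biallelic_snp
  ok_mq <- is.na(meta$mq) | meta$mq >= mq_min
  ok_dp <- meta$dp >= dp_min
  call_rate <- rowMeans(x$callable)
  ok_cr <- call_rate > call_rate_min
  first_fail <- rep(0L, nrow(meta))
  first_fail[!ok_cr] <- 4L
  first_fail[!ok_dp] <- 3L
  first_fail[!ok_mq] <- 2L
  first_fail[!ok_class] <- 1L
  tally <- c(allele_class = sum(first_fail == 1L),
             mq = sum(first_fail == 2L),
             dp = sum(first_fail == 3L),
             call_rate = sum(first_fail == 4L))
  keep <- first_fail == 0L
  new_sweep_sites(meta[keep], x$ad_ref[keep, , drop = FALSE],
                  x$ad_alt[keep, , drop = FALSE],
                  x$gt[keep, , drop = FALSE],
                  x$callable[keep, , drop = FALSE],
                  x$assignment, x$source, filtered = TRUE,
                  drop_tally = tally)
}

#' Per-rule drop counts from the last [filter_sites()] call
#' @param x a filtered `sweep_sites` object.
#' @return named integer vector (allele_class, mq, dp, call_rate).
#' @export
drop_tally <- function(x) x$drop_tally

#' Per-group major/minor allele read counts
#'
#' Within each group, ref and alt reads are summed over the group's samples
#' at every site; the larger sum is n_MAJ and the smaller n_MIN. The major
#' allele is determined independently per group and may differ between
#' groups at the same site. For individual-mode groups without usable AD,
#' genotype-derived pseudo-counts are used (each called diploid contributes
#' two allele observations); this is recorded in the `counts_source`
#' attribute.
#'
#' @param x a `sweep_sites` object (normally after [filter_sites()]).
#' @return a `group_counts` data.table: chrom, pos and per group `ref_<g>`,
#'   `alt_<g>`, `nmaj_<g>`, `nmin_<g>`, `informative_<g>` columns. The group
#'   names are in `attr(, "groups")`.
#' @export
group_counts <- function(x) {
  stopifnot(inherits(x, "sweep_sites"))
  asn <- x$assignment
  groups <- unique(asn$group)
  out <- data.table(chrom = x$meta$chrom, pos = x$meta$pos)
  src <- character(0)
  for (g in groups) {
    cols <- asn[group == g, sample_id]
    gmode <- asn[group == g, mode][1]
    use_ad <- any(x$ad_ref[, cols, drop = FALSE] +
                  x$ad_alt[, cols, drop = FALSE] > 0L)
    if (gmode == "pooled" || use_ad) {
      r <- rowSums(x$ad_ref[, cols, drop = FALSE])
      a <- rowSums(x$ad_alt[, cols, drop = FALSE])
      src[g] <- "AD"
    } else {
      gts <- x$gt[, cols, drop = FALSE]
      a <- rowSums(gts, na.rm = TRUE)
      r <- 2L * rowSums(!is.na(gts)) - a
      src[g] <- "GT"
    }
    r <- as.numeric(r); a <- as.numeric(a)
    set(out, j = paste0("ref_", g), value = r)
    set(out, j = paste0("alt_", g), value = a)
    set(out, j = paste0("nmaj_", g), value = pmax(r, a))
    set(out, j = paste0("nmin_", g), value = pmin(r, a))
    set(out, j = paste0("informative_", g), value = (r + a) > 0)
  }
  setattr(out, "groups", groups)
  setattr(out, "counts_source", src)
  setattr(out, "n_diploids",
          vapply(groups, function(g) {
            gmode <- asn[group == g, mode][1]
            if (gmode == "individual") sum(asn$group == g) else NA_integer_
          }, 1L))
  out[]
}
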