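# End-to-end commands: simulate, scan, concord. Each writes plain-text
# outputs (TSV/BED/JSON) into an output directory, logs per-stage counts to
# stderr, and embeds the grid parameters in every window table so the
# concordance step can verify compatibility.

#' Read chromosome lengths from a FASTA index or 2-column TSV
#'
#' Accepts a samtools `.fai` (name, length, ... columns) or any tab file
#' whose first two columns are chromosome name and length.
#'
#' @param path file path.
#' @return named numeric vector of lengths.
#' @export
read_chrom_lengths <- function(path) {
  dt <- fread(path, header = FALSE, sep = "\t")
  if (ncol(dt) < 2L) stop("need at least 2 columns (chrom, length)")
  stats::setNames(as.numeric(dt[[2]]), as.character(dt[[1]]))
}

#' Write / read a window statistics table with embedded grid parameters
#'
#' Grid parameters travel as `#key=value` comment lines above the header,
#' so a re-loaded table can be checked for grid compatibility by
#' [match_windows()].
#'
#' @param stats window table from [scan_sweeps()].
#' @param path TSV path.
#' @return `write_scan_table`: invisibly, the path. `read_scan_table`: the
#'   table with window_size / window_step / n_tested attributes restored.
#' @export
write_scan_table <- function(stats, path) {
  hdr <- c(sprintf("#window_size=%d", attr(stats, "window_size")),
           sprintf("#window_step=%d", attr(stats, "window_step")),
           sprintf("#min_snps=%d", attr(stats, "min_snps")),
           sprintf("#n_tested=%d", attr(stats, "n_tested")),
           sprintf("#contrast=%s", paste(attr(stats, "contrast"),
                                         collapse = ",")))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr[!grepl("=$", hdr)], con)
  write.table(as.data.frame(stats), con, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_scan_table
#' @export
read_scan_table <- function(path) {
  lines <- readLines(path, n = 50L)
  meta <- grep("^#[a-z_]+=", lines, value = TRUE)
  kv <- strsplit(sub("^#", "", meta), "=", fixed = TRUE)
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, `[`, "", 2L)
  dt <- fread(path, skip = length(meta), header = TRUE, sep = "\t")
  for (k in c("window_size", "window_step", "min_snps", "n_tested"))
    if (k %in% keys) setattr(dt, k, as.integer(vals[keys == k]))
  if ("contrast" %in% keys)
    setattr(dt, "contrast", strsplit(vals[keys == "contrast"], ",")[[1]])
  dt[]
}

.write_bed <- function(dt, path, extra_cols = character()) {
  if (nrow(dt)) {
    cols <- cbind(dt$chrom, dt$start - 1L, dt$end,
                  if (length(extra_cols))
                    do.call(cbind, lapply(extra_cols, function(cc)
                      as.character(dt[[cc]]))))
    writeLines(apply(cols, 1L, paste, collapse = "\t"), path)
  } else writeLines(character(), path)
  invisible(path)
}

#' Simulate a dataset and write all pipeline inputs
#'
#' Wraps the synthetic-data module end to end: simulates under `config`,
#' writes the VCF, truth BED, group TSV and chromosome-length TSV into
#' `out_dir`, plus a JSON manifest with the seed, key parameters and md5
#' checksums of every file. Identical config and seed give identical
#' checksums.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a named list of output paths plus the manifest.
#' @export
run_simulate <- function(config, out_dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_dataset(config)
  paths <- write_simulated_vcf(
    sim,
    vcf_path = file.path(out_dir, "sim.vcf"),
    bed_path = file.path(out_dir, "sim.truth.bed"),
    groups_path = file.path(out_dir, "sim.groups.tsv"),
    lengths_path = file.path(out_dir, "sim.chroms.tsv"))
  manifest <- list(
    seed = config$seed,
    n_sites = nrow(sim$sites),
    snp_density = config$snp_density,
    error_rate = config$error_rate,
    chrom_lengths = as.list(config$chrom_lengths),
    groups = lapply(config$groups, function(g)
      g[c("mode", "n_samples", "divergence")]),
    n_sweeps = length(config$sweeps),
    md5 = as.list(tools::md5sum(unlist(paths))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  message(sprintf("[simulate] %d sites, %d samples -> %s",
                  nrow(sim$sites), nrow(sim$samples), out_dir))
  invisible(c(paths, list(manifest = file.path(out_dir, "manifest.json"),
                          sim = sim)))
}

#' Run the full sweep scan on a VCF
#'
#' Stages, in order: read sites, apply quality filters, build the window
#' grid, aggregate per-group counts, compute Hp/ZHp/dZHp/FST, call
#' outliers. Writes `windows.tsv` (per-window statistics with grid header),
#' `calls_threshold.bed` (|dZHp| beyond `zthr`), `calls_bonferroni.bed`
#' (family-wise `alpha`), and `summary.json` with per-stage tallies.
#'
#' @param vcf VCF path.
#' @param groups_file sample/group/mode TSV (see [read_group_file()]).
#' @param chrom_lengths_file `.fai` or 2-column TSV of chromosome lengths.
#' @param out_dir output directory.
#' @param window_size,window_step,min_snps grid parameters.
#' @param mq_min,dp_min,call_rate_min site filters (see [filter_sites()]).
#' @param contrast,fst_n_cap,restandardize passed to [scan_sweeps()].
#' @param zthr,alpha outlier thresholds for the two call sets.
#' @return invisibly: list with the stats table, both call sets, the
#'   summary list and output paths.
#' @export
run_scan <- function(vcf, groups_file, chrom_lengths_file, out_dir,
                     window_size = 150000L, window_step = 75000L,
                     min_snps = 20L, mq_min = 50, dp_min = 5,
                     call_rate_min = 0.90, contrast = NULL,
                     fst_n_cap = NULL, restandardize = FALSE,
                     zthr = 3, alpha = 0.05) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  asn <- read_group_file(groups_file)
  sites <- read_sites(vcf, asn)
  message(sprintf("[scan] %d sites read from %s", n_sites(sites), vcf))
  scan_core(sites, read_chrom_lengths(chrom_lengths_file), out_dir,
            window_size, window_step, min_snps, mq_min, dp_min,
            call_rate_min, contrast, fst_n_cap, restandardize, zthr, alpha)
}

# shared by run_scan() (VCF input) and in-memory simulation studies
scan_core <- function(sites, chrom_lengths, out_dir = NULL,
                      window_size = 150000L, window_step = 75000L,
                      min_snps = 20L, mq_min = 50, dp_min = 5,
                      call_rate_min = 0.90, contrast = NULL,
                      fst_n_cap = NULL, restandardize = FALSE,
                      zthr = 3, alpha = 0.05) {
  n_read <- n_sites(sites)
  flt <- filter_sites(sites, mq_min, dp_min, call_rate_min)
  message(sprintf("[scan] filters: %d read, %d retained (dropped: %s)",
                  n_read, n_sites(flt),
                  paste(names(drop_tally(flt)), drop_tally(flt),
                        sep = "=", collapse = ", ")))
  counts <- group_counts(flt)
  windows <- make_windows(chrom_lengths, window_size, window_step)
  if (n_sites(flt) == 0L)
    warning("no sites left after filtering; outputs will be empty",
            call. = FALSE)
  stats <- scan_sweeps(counts, windows, contrast = contrast,
                       min_snps = min_snps, fst_n_cap = fst_n_cap,
                       restandardize = restandardize)
  calls_thr <- outlier_windows(stats, mode = "zthr", zthr = zthr)
  calls_bon <- outlier_windows(stats, mode = "alpha", alpha = alpha)
  nsig_thr <- attr(calls_thr, "n_significant_windows")
  nsig_bon <- attr(calls_bon, "n_significant_windows")
  summary <- list(
    sites_read = n_read,
    sites_retained = n_sites(flt),
    dropped = as.list(drop_tally(flt)),
    windows_grid = nrow(windows),
    windows_tested = attr(stats, "n_tested"),
    contrast = attr(stats, "contrast"),
    threshold = list(zthr = zthr,
                     windows_upper = unname(nsig_thr["upper"]),
                     windows_lower = unname(nsig_thr["lower"])),
    bonferroni = list(alpha = alpha,
                      windows_upper = unname(nsig_bon["upper"]),
                      windows_lower = unname(nsig_bon["lower"])))
  message(sprintf(
    "[scan] %d/%d windows tested; |dZHp|>%g: %d up / %d down; Bonferroni: %d up / %d down",
    summary$windows_tested, summary$windows_grid, zthr,
    nsig_thr["upper"], nsig_thr["lower"],
    nsig_bon["upper"], nsig_bon["lower"]))
  paths <- NULL
  if (!is.null(out_dir)) {
    paths <- list(windows = file.path(out_dir, "windows.tsv"),
                  calls_threshold = file.path(out_dir, "calls_threshold.bed"),
                  calls_bonferroni = file.path(out_dir, "calls_bonferroni.bed"),
                  summary = file.path(out_dir, "summary.json"))
    write_scan_table(stats, paths$windows)
    .write_bed(calls_thr, paths$calls_threshold,
               c("direction", "n_windows", "peak_score"))
    .write_bed(calls_bon, paths$calls_bonferroni,
               c("direction", "n_windows", "min_p_adj"))
    jsonlite::write_json(summary, paths$summary, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(list(stats = stats, calls_threshold = calls_thr,
                 calls_bonferroni = calls_bon, summary = summary,
                 paths = paths))
}

#' Cross-dataset concordance report
#'
#' Loads two scan output directories, aligns their window tables, runs the
#' rank-shift test of dataset A's threshold-outlier windows against the
#' farmed-group homozygosity in dataset B, intersects the
#' Bonferroni-significant window sets into shared regions, and correlates
#' the dZHp profiles. Writes `shared_regions.bed`, `scatter.tsv` (aligned
#' dZHp pairs) and `concordance.json`.
#'
#' @param dir_a,dir_b scan output directories (from [run_scan()]).
#' @param out_dir output directory.
#' @param zthr candidate threshold applied to dataset A's dZHp.
#' @param alpha Bonferroni family-wise rate for the intersection.
#' @return invisibly: list with the report, aligned table and shared
#'   regions.
#' @export
run_concord <- function(dir_a, dir_b, out_dir, zthr = 3, alpha = 0.05) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ta <- read_scan_table(file.path(dir_a, "windows.tsv"))
  tb <- read_scan_table(file.path(dir_b, "windows.tsv"))
  m <- match_windows(ta, tb)
  aligned <- m[!is.na(delta_zhp_a) & !is.na(delta_zhp_b)]

  contrast_b <- attr(tb, "contrast")
  farmed_b <- paste0("zhp_", contrast_b[2], "_b")
  candidate <- aligned$delta_zhp_a > zthr
  rst <- if (any(candidate) && !all(candidate))
    rank_shift_test(-aligned[[farmed_b]], candidate)
  else list(p = NA_real_, method = "skipped: no candidates or no background",
            n_candidate = sum(candidate),
            n_background = sum(!candidate), degenerate = NA)

  sig_a <- outlier_windows(ta, mode = "alpha", alpha = alpha, merge = FALSE)
  sig_b <- outlier_windows(tb, mode = "alpha", alpha = alpha, merge = FALSE)
  shared <- intersect_significant(sig_a, sig_b)
  corr <- if (nrow(aligned) >= 3L &&
              sd(aligned$delta_zhp_a) > 0 && sd(aligned$delta_zhp_b) > 0)
    delta_correlation(aligned$delta_zhp_a, aligned$delta_zhp_b)
  else list(r = NA_real_, r2 = NA_real_, p = NA_real_, n = nrow(aligned))

  report <- list(
    windows_matched = nrow(m),
    a_only = attr(m, "n_a_only"), b_only = attr(m, "n_b_only"),
    rank_shift = rst[c("p", "n_candidate", "n_background", "method")],
    shared_regions = nrow(shared),
    shared_windows = attr(shared, "n_shared_windows"),
    correlation = corr)
  .write_bed(shared, file.path(out_dir, "shared_regions.bed"),
             c("direction", "n_windows"))
  fwrite(aligned[, .(chrom, start, end, delta_zhp_a, delta_zhp_b)],
         file.path(out_dir, "scatter.tsv"), sep = "\t")
  jsonlite::write_json(report, file.path(out_dir, "concordance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  message(sprintf(
    "[concord] %d matched windows; rank-shift p = %s; %d shared regions; r2 = %s",
    nrow(m), format(rst$p, digits = 4), nrow(shared),
    format(corr$r2, digits = 4)))
  invisible(list(report = report, aligned = aligned, shared = shared))
}
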