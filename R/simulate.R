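# Synthetic pool-seq / individual-seq data generator.
#
# The generator emulates the statistical structure the sweep scan assumes:
# two groups diverged from a common ancestral population under a
# Balding-Nichols model, SNPs placed as a Poisson process along each
# chromosome, reads drawn by two-stage binomial sampling (finite pool of
# 2N chromosomes, then sequencing depth), and optional sweep regions in
# which one group is pushed toward fixation.

#' Describe a group of pooled samples
#'
#' @param n_pools number of pools in the group.
#' @param n_diploids diploid individuals per pool (recycled to `n_pools`).
#' @param mean_depth mean sequencing depth per pool at a site (recycled).
#' @param divergence Balding-Nichols divergence F of this group from the
#'   ancestral population; 0 <= F < 1. F = 0 reproduces the ancestral
#'   frequency exactly.
#' @return a list describing the group, for use in [sim_config()].
#' @export
pool_group <- function(n_pools, n_diploids, mean_depth, divergence = 0.03) {
  stopifnot(n_pools >= 1, all(n_diploids >= 1), all(mean_depth > 0),
            divergence >= 0, divergence < 1)
  list(mode = "pooled",
       n_samples = as.integer(n_pools),
       n_diploids = rep_len(as.integer(n_diploids), n_pools),
       mean_depth = rep_len(as.numeric(mean_depth), n_pools),
       divergence = divergence)
}

#' Describe a group of individually sequenced samples
#'
#' @param n_individuals number of diploid individuals.
#' @param mean_depth mean sequencing depth per individual (recycled).
#' @inheritParams pool_group
#' @return a list describing the group, for use in [sim_config()].
#' @export
indiv_group <- function(n_individuals, mean_depth, divergence = 0.03) {
  stopifnot(n_individuals >= 1, all(mean_depth > 0),
            divergence >= 0, divergence < 1)
  list(mode = "individual",
       n_samples = as.integer(n_individuals),
       n_diploids = rep_len(1L, n_individuals),
       mean_depth = rep_len(as.numeric(mean_depth), n_individuals),
       divergence = divergence)
}

#' Specify a sweep region for the simulator
#'
#' Inside the interval, each SNP is driven to fixation in the target group
#' independently with probability `f`. Fixation is toward the ancestral
#' major allele, mimicking loss of the minor haplotype.
#'
#' @param chrom chromosome name.
#' @param start,end interval in bp, 1-based inclusive.
#' @param group target group name.
#' @param f per-SNP fixation probability in `[0, 1]`.
#' @return a `sweep_spec` list.
#' @export
sweep_spec <- function(chrom, start, end, group, f = 0.95) {
  stopifnot(is.character(chrom), length(chrom) == 1L,
            start >= 1, end >= start, f >= 0, f <= 1,
            is.character(group), length(group) == 1L)
  structure(list(chrom = chrom, start = as.integer(start),
                 end = as.integer(end), group = group, f = f),
            class = "sweep_spec")
}

#' Build a simulation configuration
#'
#' Defaults mirror a desk-scale analogue of a farmed-vs-wild Atlantic salmon
#' pool-seq contrast: 4 farmed pools of 22 diploids and 6 wild pools of 20
#' diploids, each sequenced to ~22x, SNP density 1/500 bp, and per-group
#' divergence F = 0.03 so the pairwise Weir-Cockerham FST falls around
#' 0.05-0.07.
#'
#' @param chrom_lengths named integer vector of chromosome lengths (bp).
#' @param groups named list of [pool_group()] / [indiv_group()] entries
#'   (>= 2 groups for a contrast scan).
#' @param snp_density expected SNPs per bp (Poisson intensity).
#' @param p0_range range of the uniform ancestral allele-frequency law.
#' @param error_rate per-read sequencing error rate (probability a read
#'   reports the other allele); 0 <= error < 0.5.
#' @param sweeps list of [sweep_spec()] objects.
#' @param seed integer random seed; a fixed seed makes all outputs
#'   byte-identical across runs.
#' @return a validated `sim_config` object.
#' @export
sim_config <- function(chrom_lengths = c(chr1 = 5e6, chr2 = 5e6),
                       groups = list(
                         farmed = pool_group(4, 22, 22),
                         wild   = pool_group(6, 20, 22)),
                       snp_density = 1 / 500,
                       p0_range = c(0.05, 0.95),
                       error_rate = 0.002,
                       sweeps = list(),
                       seed = 1L) {
  if (is.null(names(chrom_lengths)) || anyDuplicated(names(chrom_lengths)))
    stop("chrom_lengths must be a uniquely named vector")
  if (any(chrom_lengths <= 0)) stop("all chromosome lengths must be > 0")
  if (snp_density <= 0) stop("snp_density must be > 0")
  if (error_rate < 0 || error_rate >= 0.5)
    stop("error_rate must be in [0, 0.5)")
  if (is.null(names(groups)) || anyDuplicated(names(groups)) ||
      length(groups) < 1)
    stop("groups must be a uniquely named, non-empty list")
  stopifnot(length(p0_range) == 2L, p0_range[1] > 0, p0_range[2] < 1,
            p0_range[1] <= p0_range[2])
  if (inherits(sweeps, "sweep_spec")) sweeps <- list(sweeps)
  for (sw in sweeps) {
    if (!inherits(sw, "sweep_spec")) stop("sweeps must be sweep_spec objects")
    if (!sw$chrom %in% names(chrom_lengths))
      stop("sweep on unknown chromosome: ", sw$chrom)
    if (sw$end > chrom_lengths[[sw$chrom]])
      stop("sweep interval exceeds chromosome length on ", sw$chrom)
    if (!sw$group %in% names(groups))
      stop("sweep targets unknown group: ", sw$group)
  }
  .check_sweep_overlap(sweeps)
  structure(list(chrom_lengths = chrom_lengths, groups = groups,
                 snp_density = snp_density, p0_range = p0_range,
                 error_rate = error_rate, sweeps = sweeps,
                 seed = as.integer(seed)),
            class = "sim_config")
}

.check_sweep_overlap <- function(sweeps) {
  if (length(sweeps) < 2) return(invisible())
  key <- vapply(sweeps, function(s) paste(s$group, s$chrom), "")
  for (k in unique(key)) {
    ss <- sweeps[key == k]
    if (length(ss) < 2) next
    iv <- data.table(start = vapply(ss, `[[`, 1L, "start"),
                     end = vapply(ss, `[[`, 1L, "end"))
    setorder(iv, start)
    if (any(iv$start[-1] <= iv$end[-nrow(iv)]))
      stop("overlapping sweeps for the same group on ", k,
           ": truth would be ambiguous")
  }
  invisible()
}

#' Simulate per-site ancestral and per-group allele frequencies
#'
#' SNP positions form a Poisson process with intensity `snp_density` on each
#' chromosome (duplicate positions collapsed). The ancestral alternate-allele
#' frequency p0 is uniform on `p0_range`; each group's frequency is drawn
#' from the Balding-Nichols Beta distribution
#' Beta(p0 (1-F)/F, (1-p0)(1-F)/F), which has mean p0 and variance
#' F p0 (1-p0). F = 0 degenerates to the point mass at p0.
#'
#' Uses the current RNG state; seed externally (or via [simulate_dataset()])
#' for reproducibility.
#'
#' @param config a [sim_config()] object.
#' @return `data.table` with columns chrom, pos, p0, and one `freq_<group>`
#'   column per group (alternate-allele frequency).
#' @export
simulate_site_frequencies <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  tabs <- lapply(names(config$chrom_lengths), function(ch) {
    L <- config$chrom_lengths[[ch]]
    n <- rpois(1L, L * config$snp_density)
    pos <- sort(unique(sample.int(L, n, replace = TRUE)))
    data.table(chrom = ch, pos = pos)
  })
  sites <- rbindlist(tabs)
  sites[, p0 := runif(.N, config$p0_range[1], config$p0_range[2])]
  for (g in names(config$groups)) {
    F <- config$groups[[g]]$divergence
    col <- paste0("freq_", g)
    if (F == 0) {
      sites[, (col) := p0]
    } else {
      k <- (1 - F) / F
      sites[, (col) := rbeta(.N, p0 * k, (1 - p0) * k)]
    }
  }
  sites[]
}

#' Impose sweep regions on a simulated site table
#'
#' For each SNP inside a sweep interval, with probability `f` the target
#' group's frequency is set to 1 if p0 >= 0.5 and to 0 otherwise (fixation
#' toward the ancestral major allele). Other entries are untouched.
#'
#' @param sites site table from [simulate_site_frequencies()].
#' @param sweeps list of [sweep_spec()] objects (overlap within a group is
#'   rejected).
#' @return modified copy of `sites`.
#' @export
apply_sweeps <- function(sites, sweeps) {
  if (inherits(sweeps, "sweep_spec")) sweeps <- list(sweeps)
  .check_sweep_overlap(sweeps)
  sites <- copy(sites)
  for (sw in sweeps) {
    col <- paste0("freq_", sw$group)
    if (!col %in% names(sites)) stop("unknown sweep target group: ", sw$group)
    idx <- sites[, which(chrom == sw$chrom & pos >= sw$start & pos <= sw$end)]
    if (!length(idx)) next
    hit <- idx[runif(length(idx)) < sw$f]
    if (length(hit))
      set(sites, hit, col, as.numeric(sites$p0[hit] >= 0.5))
  }
  sites[]
}

#' Truth regions for a set of sweeps
#'
#' @param sweeps list of [sweep_spec()] objects.
#' @return `data.table` (chrom, start, end, group, f), 1-based inclusive;
#'   [write_simulated_vcf()] converts to 0-based half-open BED on disk.
#' @export
truth_regions <- function(sweeps) {
  if (inherits(sweeps, "sweep_spec")) sweeps <- list(sweeps)
  if (!length(sweeps))
    return(data.table(chrom = character(), start = integer(),
                      end = integer(), group = character(), f = numeric()))
  rbindlist(lapply(sweeps, function(s)
    data.table(chrom = s$chrom, start = s$start, end = s$end,
               group = s$group, f = s$f)))
}

# read-error flip: observed alt reads given true alt reads and depth
.flip_reads <- function(alt_true, depth, eps) {
  if (eps == 0) return(alt_true)
  rbinom(length(alt_true), alt_true, 1 - eps) +
    rbinom(length(alt_true), depth - alt_true, eps)
}

#' Sample pooled read counts for one group
#'
#' Two-stage sampling: the pool's realized allele composition is
#' Binomial(2 n_diploids, freq) / (2 n_diploids); the site depth is
#' Poisson(mean_depth); alternate-allele reads are Binomial(depth,
#' composition); each read is flipped with probability `error_rate`.
#' Depth 0 is recorded as missing (both counts 0).
#'
#' @param freq numeric vector of the group's per-site alternate-allele
#'   frequencies.
#' @param group a [pool_group()] description.
#' @param error_rate per-read error rate.
#' @return list of integer matrices `ref` and `alt` (sites x pools).
#' @export
sample_pool_reads <- function(freq, group, error_rate = 0) {
  stopifnot(identical(group$mode, "pooled"))
  n <- length(freq)
  ref <- alt <- matrix(0L, n, group$n_samples)
  for (j in seq_len(group$n_samples)) {
    chrom2n <- 2L * group$n_diploids[j]
    comp <- rbinom(n, chrom2n, freq) / chrom2n
    depth <- rpois(n, group$mean_depth[j])
    alt_true <- rbinom(n, depth, comp)
    alt_obs <- .flip_reads(alt_true, depth, error_rate)
    alt[, j] <- as.integer(alt_obs)
    ref[, j] <- as.integer(depth - alt_obs)
  }
  list(ref = ref, alt = alt)
}

#' Sample genotypes and read counts for an individually sequenced group
#'
#' Genotypes are Binomial(2, freq) (Hardy-Weinberg); per-individual site
#' depth is Poisson(mean_depth); allele depths are binomial given the
#' genotype with per-read error `error_rate`. Depth 0 yields a missing call
#' (genotype NA).
#'
#' @inheritParams sample_pool_reads
#' @param group an [indiv_group()] description.
#' @return list of matrices `gt` (alt-allele dosage 0/1/2, NA = no call),
#'   `ref`, `alt` (sites x individuals).
#' @export
sample_individual_genotypes <- function(freq, group, error_rate = 0) {
  stopifnot(identical(group$mode, "individual"))
  n <- length(freq)
  gt <- ref <- alt <- matrix(0L, n, group$n_samples)
  for (j in seq_len(group$n_samples)) {
    g <- rbinom(n, 2L, freq)
    depth <- rpois(n, group$mean_depth[j])
    alt_true <- rbinom(n, depth, g / 2)
    alt_obs <- .flip_reads(alt_true, depth, error_rate)
    g[depth == 0L] <- NA_integer_
    gt[, j] <- g
    alt[, j] <- as.integer(alt_obs)
    ref[, j] <- as.integer(depth - alt_obs)
  }
  list(gt = gt, ref = ref, alt = alt)
}

#' Run the full simulator in memory
#'
#' Seeds the RNG from `config$seed`, draws site frequencies, applies sweeps
#' and samples reads/genotypes for every group. The result can be written to
#' disk with [write_simulated_vcf()] or scanned directly with
#' [sim_as_sites()] + [scan_sweeps()].
#'
#' @param config a [sim_config()] object.
#' @return a `sim_dataset` list: `sites` (site table with frequencies),
#'   `samples` (data.table sample_id/group/mode), `ref`, `alt`, `gt`
#'   matrices over all samples, `truth` region table, and `config`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  sites <- simulate_site_frequencies(config)
  sites <- apply_sweeps(sites, config$sweeps)
  n <- nrow(sites)
  samples <- rbindlist(lapply(names(config$groups), function(g) {
    grp <- config$groups[[g]]
    data.table(sample_id = sprintf("%s_%02d", g, seq_len(grp$n_samples)),
               group = g, mode = grp$mode)
  }))
  ref <- alt <- matrix(0L, n, nrow(samples),
                       dimnames = list(NULL, samples$sample_id))
  gt <- matrix(NA_integer_, n, nrow(samples),
               dimnames = list(NULL, samples$sample_id))
  for (g in names(config$groups)) {
    grp <- config$groups[[g]]
    freq <- sites[[paste0("freq_", g)]]
    cols <- samples[group == g, sample_id]
    if (grp$mode == "pooled") {
      rd <- sample_pool_reads(freq, grp, config$error_rate)
    } else {
      rd <- sample_individual_genotypes(freq, grp, config$error_rate)
      gt[, cols] <- rd$gt
    }
    ref[, cols] <- rd$ref
    alt[, cols] <- rd$alt
  }
  structure(list(sites = sites, samples = samples, ref = ref, alt = alt,
                 gt = gt, truth = truth_regions(config$sweeps),
                 config = config),
            class = "sim_dataset")
}

.gt_string <- function(gt, ref, alt) {
  # individuals: from dosage; pools: from observed allele presence
  out <- character(length(ref))
  dp <- ref + alt
  if (all(is.na(gt))) {
    out[dp == 0L] <- "./."
    out[dp > 0L & alt == 0L] <- "0/0"
    out[dp > 0L & ref == 0L] <- "1/1"
    out[ref > 0L & alt > 0L] <- "0/1"
  } else {
    out[is.na(gt)] <- "./."
    out[!is.na(gt)] <- c("0/0", "0/1", "1/1")[gt[!is.na(gt)] + 1L]
  }
  out
}

#' Write a simulated dataset as VCF plus companion files
#'
#' Emits a VCF 4.2 with per-sample GT, DP and AD fields, a truth BED
#' (0-based half-open, with group and f columns), a sample-to-group TSV and
#' a 2-column chromosome-length TSV. Output is byte-identical under a fixed
#' simulation seed.
#'
#' @param sim a `sim_dataset` from [simulate_dataset()].
#' @param vcf_path output VCF path.
#' @param bed_path output truth-BED path (default alongside the VCF).
#' @param groups_path output sample/group/mode TSV path.
#' @param lengths_path output chromosome-length TSV path.
#' @return invisibly, a named list of the written paths.
#' @export
write_simulated_vcf <- function(sim, vcf_path,
                                bed_path = sub("\\.vcf$", ".truth.bed", vcf_path),
                                groups_path = sub("\\.vcf$", ".groups.tsv", vcf_path),
                                lengths_path = sub("\\.vcf$", ".chroms.tsv", vcf_path)) {
  stopifnot(inherits(sim, "sim_dataset"))
  cl <- sim$config$chrom_lengths
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=sweepscan_simulate",
    sprintf("##contig=<ID=%s,length=%d>", names(cl), as.integer(cl)),
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS mapping quality\">",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Sample read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths (ref,alt)\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sim$samples$sample_id), collapse = "\t"))
  n <- nrow(sim$sites)
  if (n > 0L) {
    dp_site <- as.integer(rowSums(sim$ref) + rowSums(sim$alt))
    cells <- matrix("", n, nrow(sim$samples))
    for (j in seq_len(nrow(sim$samples))) {
      r <- sim$ref[, j]; a <- sim$alt[, j]
      cells[, j] <- sprintf("%s:%d:%d,%d",
                            .gt_string(sim$gt[, j], r, a), r + a, r, a)
    }
    body <- paste(sim$sites$chrom, sim$sites$pos, ".", "A", "C", ".", "PASS",
                  sprintf("MQ=60;DP=%d", dp_site), "GT:DP:AD",
                  apply(cells, 1L, paste, collapse = "\t"), sep = "\t")
  } else body <- character()
  writeLines(c(hdr, body), vcf_path)

  tr <- sim$truth
  bed <- if (nrow(tr)) sprintf("%s\t%d\t%d\t%s\t%g", tr$chrom,
                               tr$start - 1L, tr$end, tr$group, tr$f)
         else character()
  writeLines(bed, bed_path)
  writeLines(c("sample\tgroup\tmode",
               sprintf("%s\t%s\t%s", sim$samples$sample_id,
                       sim$samples$group, sim$samples$mode)), groups_path)
  writeLines(sprintf("%s\t%d", names(cl), as.integer(cl)), lengths_path)
  invisible(list(vcf = vcf_path, truth_bed = bed_path,
                 groups = groups_path, chrom_lengths = lengths_path))
}

#' Convert an in-memory simulated dataset to scan-ready sites
#'
#' Produces the same `sweep_sites` object [read_sites()] would return after
#' writing the dataset to VCF and reading it back; useful for fast
#' simulation studies that skip disk I/O.
#'
#' @param sim a `sim_dataset` from [simulate_dataset()].
#' @return a `sweep_sites` object.
#' @export
sim_as_sites <- function(sim) {
  stopifnot(inherits(sim, "sim_dataset"))
  asn <- group_assignment(sim$samples$sample_id, sim$samples$group,
                          sim$samples$mode)
  n <- nrow(sim$sites)
  meta <- data.table(chrom = sim$sites$chrom, pos = sim$sites$pos,
                     ref = rep("A", n), alt = rep("C", n),
                     biallelic_snp = rep(TRUE, n),
                     mq = rep(60, n),
                     dp = as.integer(rowSums(sim$ref) + rowSums(sim$alt)))
  callable <- (sim$ref + sim$alt) > 0L
  new_sweep_sites(meta, ad_ref = sim$ref, ad_alt = sim$alt, gt = sim$gt,
                  callable = callable, assignment = asn,
                  source = "simulation")
}
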