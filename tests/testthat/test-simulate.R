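# Synthetic-data generator: frequency model, sweeps, read sampling, VCF
# round trip, determinism.

test_that("config validation rejects bad parameters", {
  expect_error(sim_config(chrom_lengths = c(chr1 = -5)), "lengths")
  expect_error(sim_config(snp_density = 0), "snp_density")
  expect_error(sim_config(error_rate = 0.5), "error_rate")
  expect_error(pool_group(4, 22, 22, divergence = 1), "divergence")
  expect_error(
    sim_config(sweeps = list(sweep_spec("chr9", 1, 100, "farmed"))),
    "unknown chromosome")
  expect_error(
    sim_config(sweeps = list(
      sweep_spec("chr1", 1e5, 3e5, "farmed"),
      sweep_spec("chr1", 2e5, 4e5, "farmed"))),
    "overlapping sweeps")
  # same interval, different groups is fine
  expect_silent(sim_config(sweeps = list(
    sweep_spec("chr1", 1e5, 3e5, "farmed"),
    sweep_spec("chr1", 1e5, 3e5, "wild"))))
})

test_that("site frequencies: Poisson placement, divergence law, determinism", {
  cfg <- small_sim_config(seed = 7)
  set.seed(cfg$seed)
  s1 <- simulate_site_frequencies(cfg)
  set.seed(cfg$seed)
  s2 <- simulate_site_frequencies(cfg)
  expect_identical(s1, s2)

  expect_false(is.unsorted(s1$pos))
  expect_false(anyDuplicated(s1$pos) > 0)
  # Poisson(L * density) count: 1 Mb / 500 -> mean 2000, sd ~45
  expect_gt(nrow(s1), 2000 - 6 * sqrt(2000))
  expect_lt(nrow(s1), 2000 + 6 * sqrt(2000))
  expect_true(all(s1$freq_farmed >= 0 & s1$freq_farmed <= 1))

  # F = 0 in both groups degenerates to the ancestral frequency
  cfg0 <- small_sim_config(seed = 7, divergence = 0)
  set.seed(7)
  s0 <- simulate_site_frequencies(cfg0)
  expect_identical(s0$freq_farmed, s0$p0)
  expect_identical(s0$freq_wild, s0$p0)
})

test_that("stronger divergence raises mean Weir-Cockerham FST", {
  theta_at <- function(F, seed) {
    cfg <- small_sim_config(seed = seed, chrom = c(chr1 = 5e6),
                            divergence = F)
    sim_mean_theta(simulate_dataset(cfg))
  }
  # ~1e4 sites per run, fixed seed pair (Monte-Carlo oracle comparison)
  expect_gt(theta_at(0.10, 11), theta_at(0.02, 11))
  # monotone non-decreasing over the F grid at a fixed seed
  means <- vapply(c(0, 0.02, 0.05, 0.10), theta_at, 1.0, seed = 12)
  expect_true(all(diff(means) >= 0))
  # F = 0, no sweeps: mean per-site theta within +/- 0.01 of 0
  expect_lt(abs(means[1]), 0.01)
})

test_that("apply_sweeps fixes the target group toward the ancestral major allele", {
  cfg <- small_sim_config(seed = 3)
  set.seed(3)
  sites <- simulate_site_frequencies(cfg)
  sw <- list(sweep_spec("chr1", 2e5, 6e5, "farmed", f = 1))

  out <- apply_sweeps(sites, sw)
  inside <- out$chrom == "chr1" & out$pos >= 2e5 & out$pos <= 6e5
  expect_true(all(out$freq_farmed[inside] %in% c(0, 1)))
  expect_identical(out$freq_farmed[inside], as.numeric(out$p0[inside] >= 0.5))
  # untouched: wild everywhere, farmed outside the interval
  expect_identical(out$freq_wild, sites$freq_wild)
  expect_identical(out$freq_farmed[!inside], sites$freq_farmed[!inside])

  # f = 0 leaves the table unchanged
  expect_identical(
    apply_sweeps(sites, list(sweep_spec("chr1", 2e5, 6e5, "farmed", f = 0))),
    sites)
})

test_that("partial sweeps fix a Binomial(n, f) number of SNPs", {
  # binomial quantile oracle: with ~n in-sweep SNPs and f = 0.5 the fixed
  # count stays within qbinom(c(5e-4, 1 - 5e-4)) across 10 seeds
  counts <- vapply(1:10, function(seed) {
    cfg <- small_sim_config(seed = seed)
    set.seed(seed)
    sites <- simulate_site_frequencies(cfg)
    sw <- list(sweep_spec("chr1", 4e5, 5e5, "farmed", f = 0.5))
    out <- apply_sweeps(sites, sw)
    inside <- out$pos >= 4e5 & out$pos <= 5e5
    n_in <- sum(inside)
    # Beta draws are continuous, so equality with the 0/1 fixation target
    # identifies exactly the fixed SNPs
    tgt <- as.numeric(out$p0[inside] >= 0.5)
    c(sum(out$freq_farmed[inside] == tgt), n_in)
  }, c(fixed = 0, n = 0))
  for (k in 1:10) {
    lo <- qbinom(5e-4, counts["n", k], 0.5)
    hi <- qbinom(1 - 5e-4, counts["n", k], 0.5)
    expect_gte(counts["fixed", k], lo)
    expect_lte(counts["fixed", k], hi)
  }
})

test_that("pool read sampling has the stated moments", {
  grp <- pool_group(1, 22, 1000)
  set.seed(5)
  # freq 1, no error: every read is the alternate allele
  rd <- sample_pool_reads(rep(1, 50), grp, error_rate = 0)
  expect_true(all(rd$ref == 0))
  expect_true(all(rd$alt > 0))
  # binomial concentration: at freq 0.5 every site's alt fraction lies
  # within +/- 0.05 of 0.5 once 0.05 is far outside the binomial sd
  # (sqrt(.25/4000) ~ 0.008, so 0.05 is >6 sd; a huge pool pins the
  # composition stage at 0.5)
  huge <- pool_group(1, 5e4, 4000)
  rd <- sample_pool_reads(rep(0.5, 20), huge, error_rate = 0)
  frac <- rd$alt / (rd$ref + rd$alt)
  expect_true(all(abs(frac - 0.5) < 0.05))
  # with a realistic 22-diploid pool the composition stage adds
  # sd sqrt(.25/44) ~ 0.075 per site, so only the mean obeys +/- 0.05
  rd <- sample_pool_reads(rep(0.5, 20), grp, error_rate = 0)
  expect_lt(abs(mean(rd$alt / (rd$ref + rd$alt)) - 0.5), 0.05)
  # Poisson depth: empirical mean within 5% of 22 over 1e4 sites
  grp22 <- pool_group(1, 22, 22)
  rd <- sample_pool_reads(runif(1e4), grp22, error_rate = 0.002)
  expect_lt(abs(mean(rd$ref + rd$alt) / 22 - 1), 0.05)
})

test_that("individual sampling: HWE genotypes, Poisson missingness", {
  grp <- indiv_group(1, 6)
  set.seed(6)
  rd <- sample_individual_genotypes(rep(0, 100), grp, error_rate = 0)
  expect_true(all(rd$gt[!is.na(rd$gt)] == 0L))
  expect_true(all(rd$alt == 0L))

  big <- indiv_group(1, 50)
  rd <- sample_individual_genotypes(rep(0.5, 1e4), big, error_rate = 0)
  expect_lt(abs(mean(rd$gt == 1L, na.rm = TRUE) - 0.5), 0.02)

  # depth mean 6 -> P(missing) = exp(-6) ~ 0.25%
  rd <- sample_individual_genotypes(runif(1e4), grp, error_rate = 0)
  expect_lt(abs(mean(is.na(rd$gt)) - exp(-6)), 3 * sqrt(exp(-6) / 1e4) + 1e-3)
})

test_that("VCF writer: determinism, empty table, truth BED", {
  cfg <- small_sim_config(
    seed = 9, chrom = c(chr1 = 3e5),
    sweeps = list(sweep_spec("chr1", 1e5, 2e5, "farmed", 0.9)))
  sim <- simulate_dataset(cfg)
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  for (d in c(d1, d2)) {
    dir.create(d, showWarnings = FALSE)
    write_simulated_vcf(simulate_dataset(cfg), file.path(d, "x.vcf"))
  }
  for (f in c("x.vcf", "x.truth.bed", "x.groups.tsv", "x.chroms.tsv"))
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))

  bed <- read.table(file.path(d1, "x.truth.bed"), sep = "\t")
  expect_equal(nrow(bed), 1L)
  expect_equal(bed$V2, 1e5 - 1)   # 0-based half-open on disk
  expect_equal(bed$V3, 2e5)
  expect_equal(bed$V4, "farmed")

  # empty site table -> header-only VCF
  empty <- sim
  empty$sites <- sim$sites[0]
  empty$ref <- sim$ref[0, , drop = FALSE]
  empty$alt <- sim$alt[0, , drop = FALSE]
  empty$gt <- sim$gt[0, , drop = FALSE]
  p <- tempfile(fileext = ".vcf")
  write_simulated_vcf(empty, p)
  lines <- readLines(p)
  expect_true(all(startsWith(lines, "#")))
})

test_that("VCF round trip reproduces simulated group counts exactly", {
  cfg <- sim_config(chrom_lengths = c(chr1 = 4e5),
                    groups = list(farmed = pool_group(2, 22, 22),
                                  wild = indiv_group(4, 8)),
                    error_rate = 0, seed = 13)
  sim <- simulate_dataset(cfg)
  p <- tempfile(fileext = ".vcf")
  paths <- write_simulated_vcf(sim, p)
  asn <- read_group_file(paths$groups)
  sites <- read_sites(p, asn)
  expect_equal(n_sites(sites), nrow(sim$sites))

  gc_disk <- group_counts(sites)
  gc_mem <- group_counts(sim_as_sites(sim))
  for (col in c("nmaj_farmed", "nmin_farmed", "nmaj_wild", "nmin_wild"))
    expect_identical(gc_disk[[col]], gc_mem[[col]])
})
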