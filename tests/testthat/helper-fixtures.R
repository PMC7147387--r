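# Shared fixtures and independent oracles, all built in code at test time.

# --- hand-crafted VCF fixtures -------------------------------------------

vcf_header <- function(samples, contigs = c(chrA = 1e6)) {
  c("##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", names(contigs),
            as.integer(contigs)),
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"MQ\">",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"DP\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"DP\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"AD\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", samples), collapse = "\t"))
}

# one record; sample_fields like "0/1:12:5,7"
vcf_record <- function(chrom, pos, ref, alt, info, sample_fields) {
  paste(c(chrom, pos, ".", ref, alt, ".", "PASS", info, "GT:DP:AD",
          sample_fields), collapse = "\t")
}

write_vcf_fixture <- function(lines, path = tempfile(fileext = ".vcf")) {
  writeLines(lines, path)
  path
}

# a pooled sample field with given (ref, alt) depths
pool_field <- function(ref, alt) {
  gt <- if (ref + alt == 0) "./." else if (alt == 0) "0/0" else
    if (ref == 0) "1/1" else "0/1"
  sprintf("%s:%d:%d,%d", gt, ref + alt, ref, alt)
}

# ten pooled samples, each (5,5) unless overridden by index -> c(ref, alt)
ten_pool_fields <- function(override = list()) {
  fields <- replicate(10, pool_field(5L, 5L))
  for (i in names(override)) {
    o <- override[[i]]
    fields[as.integer(i)] <- pool_field(o[1], o[2])
  }
  fields
}

ten_pool_assignment <- function() {
  group_assignment(sprintf("s%02d", 1:10),
                   rep(c("farmed", "wild"), each = 5), "pooled")
}

# --- independent oracles --------------------------------------------------

# Weir-Cockerham theta from the defining sums, written as literal scalar
# arithmetic (independent of the vectorized implementation under test)
bf_theta <- function(p1, p2, n1, n2) {
  r <- 2
  nbar <- (n1 + n2) / r
  pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
  msp <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / (r - 1)
  msg <- (n1 * p1 * (1 - p1) + n2 * p2 * (1 - p2)) /
    ((n1 - 1) + (n2 - 1))
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  den <- msp + (nc - 1) * msg
  if (den <= 0) return(NA_real_)
  (msp - msg) / den
}

# mean per-site theta between two groups of a simulated dataset, computed
# straight from the sampled read matrices
sim_mean_theta <- function(sim, g1 = "farmed", g2 = "wild") {
  s1 <- sim$samples[group == g1, sample_id]
  s2 <- sim$samples[group == g2, sample_id]
  r1 <- rowSums(sim$ref[, s1, drop = FALSE])
  a1 <- rowSums(sim$alt[, s1, drop = FALSE])
  r2 <- rowSums(sim$ref[, s2, drop = FALSE])
  a2 <- rowSums(sim$alt[, s2, drop = FALSE])
  fc <- wc_fst_site(a1 / pmax(r1 + a1, 1), a2 / pmax(r2 + a2, 1),
                    r1 + a1, r2 + a2)
  mean(fc$theta, na.rm = TRUE)
}

# small default config for fast simulation tests (1 Mb, two pooled groups)
small_sim_config <- function(seed, sweeps = list(), chrom = c(chr1 = 1e6),
                             divergence = 0.03) {
  sim_config(chrom_lengths = chrom,
             groups = list(
               farmed = pool_group(4, 22, 22, divergence),
               wild = pool_group(6, 20, 22, divergence)),
             sweeps = sweeps, seed = seed)
}

# scan an in-memory simulated dataset (no disk I/O); returns scan_core list
scan_sim <- function(sim, ...) {
  suppressMessages(
    sweepscan:::scan_core(sim_as_sites(sim), sim$config$chrom_lengths,
                          out_dir = NULL, ...))
}
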