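# Hp, Z-transform, dZHp, Weir-Cockerham FST and outlier calling.

test_that("window Hp: worked values and bounds", {
  expect_equal(window_hp(10, 10), 0.5)
  expect_equal(window_hp(c(30, 20), c(10, 20)), 3000 / 6400)  # 0.46875
  expect_equal(window_hp(c(12, 7), c(0, 0)), 0)
  expect_warning(expect_true(is.na(window_hp(0, 0))), "no reads")

  # property: Hp in [0, 0.5], = 0.5 iff sums balance, scale-invariant
  set.seed(41)
  for (i in 1:200) {
    nmaj <- rpois(10, 30); nmin <- pmin(nmaj, rpois(10, 10))
    h <- window_hp(nmaj, nmin)
    expect_gte(h, 0); expect_lte(h, 0.5)
    expect_equal(window_hp(nmaj * 7, nmin * 7), h)
  }
  expect_equal(window_hp(c(5, 10), c(10, 5)), 0.5)
})

test_that("z_transform: hand-computed values and standardization contract", {
  expect_equal(z_transform(c(0.1, 0.2, 0.3)), c(-1, 0, 1))
  expect_equal(z_transform(c(5, 5, 7, 7)),
               c(-0.8660254, -0.8660254, 0.8660254, 0.8660254),
               tolerance = 1e-7)
  set.seed(42)
  for (i in 1:20) {
    z <- z_transform(runif(50))
    expect_lt(abs(mean(z)), 1e-9)
    expect_lt(abs(sd(z) - 1), 1e-9)
  }
  expect_error(z_transform(c(2, 2, 2)), "degenerate")
  expect_error(z_transform(1), ">= 2 values")
})

test_that("delta_zhp is the wild-minus-farmed contrast and antisymmetric", {
  expect_equal(delta_zhp(2.79, -3.00), 5.79)
  set.seed(43)
  a <- rnorm(30); b <- rnorm(30)
  expect_equal(delta_zhp(a, b), -delta_zhp(b, a))
  expect_equal(delta_zhp(a, a), rep(0, 30))
  expect_error(delta_zhp(a, b[1:10]), "mismatched window sets")
  expect_error(delta_zhp(c(x = 1, y = 2), c(y = 1, x = 2)),
               "mismatched window sets")
})

test_that("Weir-Cockerham theta: closed forms and brute-force agreement", {
  # fixed difference
  expect_equal(wc_fst_site(1, 0, 50, 50)$theta, 1)
  # p1 = p2 with heterozygosity: theta = -1/(n_c - 1)
  t0 <- wc_fst_site(0.3, 0.3, 50, 50)
  expect_equal(t0$theta, -1 / 49)
  t1 <- wc_fst_site(0.5, 0.5, 80, 20)
  nc <- 100 - (80^2 + 20^2) / 100
  expect_equal(t1$theta, -1 / (nc - 1))
  # monomorphic -> undefined with zero components
  m <- wc_fst_site(0, 0, 50, 50)
  expect_false(m$defined)
  expect_equal(m$num, 0); expect_equal(m$den, 0)

  # brute-force oracle on random instances
  set.seed(44)
  for (i in 1:250) {
    p1 <- runif(1); p2 <- runif(1)
    n1 <- sample(2:500, 1); n2 <- sample(2:500, 1)
    got <- wc_fst_site(p1, p2, n1, n2)
    want <- bf_theta(p1, p2, n1, n2)
    if (got$defined) expect_equal(got$theta, want, tolerance = 1e-12)
  }
})

test_that("window FST is a ratio of sums over defined sites", {
  s <- wc_fst_site(c(1, 0.3), c(0, 0.3), c(50, 50), c(50, 50))
  expect_equal(wc_fst_window(s$num, s$den, s$defined),
               sum(s$num) / sum(s$den))
  # single defined site degenerates to that site's theta
  one <- wc_fst_site(0.9, 0.2, 40, 60)
  expect_equal(wc_fst_window(one$num, one$den, one$defined), one$theta)
  # all fixed differences -> 1
  fx <- wc_fst_site(c(1, 1, 0), c(0, 0, 1), 30, 30)
  expect_equal(wc_fst_window(fx$num, fx$den, fx$defined), 1)
  # nothing defined -> NA
  und <- wc_fst_site(c(0, 1), c(0, 1), 30, 30)
  expect_true(is.na(wc_fst_window(und$num, und$den, und$defined)))
})

test_that("outlier calling: tail p-values, Bonferroni, run merging", {
  # normal CDF oracle: z = 3 -> one-sided p = 0.00135
  expect_equal(pnorm(3, lower.tail = FALSE), 0.00135, tolerance = 1e-2)
  st <- data.table::data.table(
    chrom = "c1",
    start = 1L + 0:9 * 75000L, end = 150000L + 0:9 * 75000L,
    delta_zhp = c(0, 0, 3.1, 3.5, 0, 0, -4, 0, qnorm(1 - 0.001), 0))
  # Bonferroni oracle: window 9 has p = 0.001, N = 10 -> p_adj = 0.01 < 0.05
  calls <- outlier_windows(st, mode = "alpha", alpha = 0.05)
  expect_equal(attr(calls, "n_significant_windows")[["upper"]], 3L)
  up <- calls[direction == "upper"]
  # windows 3 and 4 overlap -> merged; window 9 stands alone
  expect_equal(nrow(up), 2L)
  expect_equal(up$start, c(150001L, 600001L))
  expect_equal(up$end, c(375000L, 750000L))
  expect_equal(up$n_windows, c(2L, 1L))
  expect_equal(up$peak_score[1], 3.5)
  expect_equal(up$min_p_adj, c(10 * pnorm(3.5, lower.tail = FALSE), 0.01))
  dn <- calls[direction == "lower"]
  expect_equal(nrow(dn), 1L)
  expect_equal(dn$peak_score, -4)

  # threshold mode, upper tail only
  thr <- outlier_windows(st, mode = "zthr", zthr = 3, direction = "upper")
  expect_equal(attr(thr, "n_significant_windows")[["upper"]], 3L)
  expect_equal(attr(thr, "n_significant_windows")[["lower"]], 0L)

  # merge = FALSE keeps one row per window
  flat <- outlier_windows(st, mode = "zthr", zthr = 3)
  expect_equal(nrow(flat[direction == "upper"]), 2L)  # merged regions
  flat2 <- outlier_windows(st, mode = "zthr", zthr = 3, merge = FALSE)
  expect_equal(nrow(flat2[direction == "upper"]), 3L)

  expect_error(outlier_windows(st, mode = "alpha", alpha = 1.2), "alpha")
  # family-wise critical value at N = 29614 one-sided tests
  expect_equal(qnorm(1 - 0.05 / 29614), 4.6475, tolerance = 1e-3)
})

test_that("scan on a simulated dataset standardizes per group and flags sweeps", {
  cfg <- small_sim_config(
    seed = 51, chrom = c(chr1 = 3e6),
    sweeps = list(sweep_spec("chr1", 1200001, 1400000, "farmed", 1)))
  sim <- simulate_dataset(cfg)
  res <- scan_sim(sim)
  st <- res$stats

  for (g in c("farmed", "wild")) {
    z <- st[[paste0("zhp_", g)]]
    expect_lt(abs(mean(z, na.rm = TRUE)), 1e-9)
    expect_lt(abs(sd(z, na.rm = TRUE) - 1), 1e-9)
  }
  # f = 1 sweep with error-free depth is not guaranteed here (eps > 0), but
  # sweep windows must sit far below the rest of the farmed distribution
  inswp <- st$start <= 1400000 & st$end >= 1200001
  full <- st$start >= 1200001 & st$end <= 1400000   # windows fully inside
  expect_true(any(full))
  q1 <- quantile(st$hp_farmed[!inswp], 0.01, na.rm = TRUE)
  expect_true(all(st$hp_farmed[full] < q1))
  # and dZHp must exceed the genome-wide 99th percentile there
  q99 <- quantile(st$delta_zhp[!inswp], 0.99, na.rm = TRUE)
  expect_true(all(st$delta_zhp[full] > q99))
  # FST elevated in the swept region relative to the genome background
  expect_gt(min(st$fst[full]), mean(st$fst[!inswp], na.rm = TRUE))
})

test_that("fully fixed sweep with error-free reads gives window Hp = 0", {
  cfg <- sim_config(chrom_lengths = c(chr1 = 1e6),
                    groups = list(farmed = pool_group(4, 22, 22),
                                  wild = pool_group(6, 20, 22)),
                    error_rate = 0,
                    sweeps = list(sweep_spec("chr1", 300001, 600000,
                                             "farmed", 1)),
                    seed = 52)
  sim <- simulate_dataset(cfg)
  st <- scan_sim(sim)$stats
  full <- st$start >= 300001 & st$end <= 600000
  expect_true(all(st$hp_farmed[full] == 0))
})
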