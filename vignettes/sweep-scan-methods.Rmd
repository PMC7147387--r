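---
title: "Methods: windowed heterozygosity sweep scans and their synthetic test world"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: windowed heterozygosity sweep scans and their synthetic test world}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model and its assumptions

`sweepscan` detects localized losses of genetic diversity by contrasting
two population groups, conventionally a domesticated ("farmed") group
against a wild one. The underlying model of a selective sweep is simple:
positive selection drives a beneficial allele and its linked neighborhood
toward fixation, so windows overlapping the sweep show depressed
polymorphism in the selected group while the unselected group retains it.

The scan statistic is pooled heterozygosity per window,

$$H_p = \frac{2\,\Sigma n_{MAJ}\,\Sigma n_{MIN}}
            {(\Sigma n_{MAJ} + \Sigma n_{MIN})^2},$$

where $n_{MAJ}$ and $n_{MIN}$ are, at each SNP, the read counts of the
group-wise most and least abundant allele, and the sums run over all SNPs
in the window **before** the ratio is taken (this is not a mean of
per-site heterozygosities; read-rich SNPs weigh more). $H_p \in [0, 0.5]$,
is maximal when the summed counts balance, and is invariant to scaling all
counts — so it works identically for deep pools and shallow individual
data. Because the major allele is chosen per group, $H_p$ needs no shared
polarization between groups.

$H_p$ is standardized genome-wide within each group over that group's
retained windows, $ZH_p = (H_p - \mu_{H_p})/\sigma_{H_p}$, and the
directional contrast is $\Delta ZH_p = ZH_{p,\mathrm{wild}} -
ZH_{p,\mathrm{farmed}}$: strongly positive where the farmed group lost
heterozygosity. As an orthogonal line of evidence the scan also aggregates
the Weir–Cockerham $\theta$ (two-population, allele-count form) over the
same windows.

Assumptions worth stating: read counts are treated as allele samples
(reasonable for pools of many diploids at moderate depth; see the
pseudo-replication cap below); windows are compared genome-wide, so the
scan assumes a broadly stationary background diversity; and the normal
tail used for p-values is an approximation discussed below.

# Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| window size | 150,000 | bp | large enough to average hundreds of SNPs, small enough to localize >100 kb sweeps |
| window step | 75,000 | bp | half-overlap halves the chance a sweep straddles window boundaries |
| min SNPs per window | 20 | SNPs | below this, $H_p$ variance is dominated by sampling noise; windows with fewer informative SNPs in a group are dropped for that group |
| site mapping quality | ≥ 50 | phred | removes ambiguous mappings (sites without MQ pass, with one warning) |
| site depth | ≥ 5 | reads | removes call-poor sites |
| call rate | > 0.90 (strict) | fraction | a site callable in exactly 90% of samples is dropped; the denominator is all assigned samples, not per group |
| outlier threshold | dZHp > 3 | z units | the conventional "suggestive" tail |
| family-wise alpha | 0.05 | — | Bonferroni over the N tested windows |

# Numerical and design choices

* **Sample standard deviation.** The Z-transform divides by the $n-1$
  standard deviation. At $\sim10^4$ windows the difference from the
  population form is negligible, but it must be pinned down for exact
  reproducibility.
* **Trailing windows are not emitted.** Only full-length windows enter the
  scan; a truncated trailing window would have a different $H_p$ variance
  and contaminate the standardization.
* **Per-group retention.** The <20-SNP discard rule is applied per group
  using that group's informative SNPs (a group with zero reads at a site
  gains no information from it); contrast statistics require retention in
  both groups. A union-count variant would retain slightly more windows
  but lets one group's noise through.
* **dZHp tail p-values.** By default dZHp is compared against a standard
  normal. The two groups' ZHp are positively correlated (they share the
  underlying diversity landscape), so
  $\mathrm{Var}(\Delta ZH_p) = 2(1-\rho) < 1$ in practice and the default
  is conservative. `restandardize = TRUE` re-standardizes the dZHp
  distribution itself before the tail lookup; this is the anti-conservative
  alternative. Neither convention reproduces every published threshold —
  e.g. a Bonferroni bound of 4.55 at N ≈ 29,614 matches neither the
  one-sided (4.65) nor two-sided (4.79) normal rule — so both tails and
  both conventions are exposed rather than hard-coding one.
* **FST estimator.** Per site, the allele-count Weir–Cockerham
  decomposition with $r = 2$; windows aggregate by the ratio of summed
  numerators to summed denominators (the weighted estimator used by
  windowed FST tools), never a mean of per-site ratios. Negative $\theta$
  is reported as computed. Monomorphic sites are undefined and excluded.
  Pool read counts serve as allele sample sizes by default; `fst_n_cap`
  caps them (e.g. at 2 × pooled diploids) to guard against
  pseudo-replication when depth exceeds the number of sampled chromosomes.
* **Ties.** If ref and alt read sums tie within a group,
  $n_{MAJ} = n_{MIN}$ and $H_p$ is unaffected (the formula is symmetric);
  the major label defaults to ref for reporting.
* **Degenerate inputs.** A window with zero reads has undefined $H_p$ and
  is flagged; a zero-variance $H_p$ vector refuses to standardize; a fully
  tied rank test returns p = 0.5 with a warning rather than a spurious
  extreme.
* **Rank-shift test.** The published validation compares candidate windows
  "with their genome-wide mean"; this is implemented as a two-sample
  Mann–Whitney of candidates versus all remaining matched windows
  (one-sided: candidates more homozygous), exact by full enumeration of
  candidate placements when both groups have ≤ 10 members (midranks handle
  ties), normal approximation with tie and continuity correction
  otherwise.
* **Individual-mode counts.** If a genotype-only VCF is supplied, each
  called diploid contributes two allele observations (pseudo-counts); the
  table records that counts came from GT rather than AD.

# What the simulator emulates — and what it does not

The generator reproduces the statistical structure the scan consumes:

* Two (or more) groups diverged from a common ancestor under the
  Balding–Nichols model: per-group allele frequency drawn from
  $\mathrm{Beta}(p_0(1-F)/F,\,(1-p_0)(1-F)/F)$ around an ancestral
  $p_0 \sim U(0.05, 0.95)$. The default per-group $F = 0.03$ was chosen
  once so that the pairwise Weir–Cockerham FST between a farmed and a wild
  group falls in the 0.05–0.07 band reported for real farmed-vs-wild
  comparisons.
* SNP positions as a Poisson process (default density 1/500 bp, which
  yields ~300 SNPs per 150 kb window — comfortably above the 20-SNP
  retention rule).
* Two-stage pool sampling: the pool's realized composition is
  $\mathrm{Binomial}(2N, p)/2N$ over its $N$ diploids, then site depth is
  Poisson (default 22×, matching 20–24× pool sequencing) and reads are
  binomial in the composition, with per-read error ε (default 0.002, a
  typical post-filter Illumina substitution rate). The composition stage
  contributes variance $p(1-p)/2N$ per pool — this is what distinguishes
  pool-seq from simply binomially thinning the population frequency, and
  it is why a per-site read fraction is not pinned to ±0.05 of the
  population frequency at finite pool size.
* Individual mode: Hardy–Weinberg genotypes, Poisson per-individual depth
  (default emulating ~6×), allele depths binomial given genotype; depth 0
  is a missing call, which feeds the >90% call-rate filter.
* Sweeps: inside a specified interval each SNP is independently driven,
  with probability $f$, to fixation toward the ancestral major allele in
  the target group. Overlapping sweeps for one group are rejected (the
  truth would be ambiguous). Truth intervals are emitted as BED.

Not emulated: recombination and linkage (fixation is independent per SNP —
sufficient because the scan consumes only site frequencies, and
block-fixation is precisely the signal the statistic detects), coalescent
demography, linked background selection, indels, multi-allelic sites, and
reference/mapping biases. A green simulation test therefore establishes
that the statistics and plumbing behave as specified on data with the
assumed sampling structure — not that the thresholds are well calibrated
for any particular real genome.

One geometric caveat encoded in the acceptance tests: a 150 kb sweep —
the minimum size exercised — fully covers a grid window only when it is
aligned to a window start; unaligned, at most 83% of any window lies
inside the sweep and the farmed ZHp dip is correspondingly diluted. Truth
sweeps in the tests are therefore placed on grid starts, so the tests
measure detection power rather than placement luck. Real sweeps are of
course not aligned; the half-overlapping grid is what bounds the worst
case.

# Determinism

A fixed simulation seed makes every output byte-identical (site tables,
VCF, BED, manifest checksums). The scan itself is deterministic. Window
tables carry their grid parameters as `#key=value` header lines so the
concordance stage can refuse to align incompatible scans.

# Known limitations

* The normal-tail p-values for dZHp inherit whatever miscalibration the
  standardization convention carries (see above); the threshold mode
  (|dZHp| > 3) is the more honest default for exploration.
* Pool-seq read counts overstate the allele sample size when depth
  approaches or exceeds 2N per pool; use `fst_n_cap`.
* The call-rate filter uses all assigned samples as denominator; datasets
  with very unequal group sizes may prefer a per-group rule, which is not
  provided.
* Windows are fixed-width; no SNP-count-equalized or adaptive windows.
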