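Package: sweepscan
Title: Selection-Sweep Scans from Pooled and Individual Resequencing Data
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects domestication-associated selection sweeps from
    multi-sample VCFs by contrasting a farmed (domesticated) group against a
    wild group. Implements windowed pooled heterozygosity (Hp), its
    genome-wide Z-transform (ZHp), the wild-minus-farmed contrast
    delta-ZHp, the Weir-Cockerham FST estimator aggregated over the same
    windows, Bonferroni-corrected outlier calling, and cross-dataset
    concordance testing (rank-shift test, window intersection, delta-ZHp
    correlation). Ships a synthetic pool-seq / individual-seq data generator
    (Balding-Nichols divergence, Poisson SNP placement, binomial read
    sampling, embedded sweeps with truth BED output) so the full analysis is
    testable at desk scale without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    methods,
    IRanges,
    GenomicRanges,
    S4Vectors,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
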