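Package: permpath
Title: Permutation-Based Differential Expression with Cross-Cohort
    Pathway Integration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Integrative two-group transcriptomic analysis for small
    whole-blood RNA-seq cohorts: expressed-gene filtering on FPKM,
    trimmed-mean-of-M-values (TMM) scaling, log2 and quantile
    normalization, per-gene t-statistics and log2 fold-changes tested
    against pooled permutation empirical nulls, Stouffer combination of
    the two empirical p-values, three-criterion differential-expression
    calls with optional percentile-derived adaptive fold-change cutoffs,
    EASE-score gene-set over-representation, and pathway-level
    integration of heterogeneous cohorts via enriched terms shared in
    every dataset. Includes a negative-binomial synthetic-cohort
    generator with planted effects and shared annotation structure,
    delta-delta-CT qPCR quantification, and clinical-table summaries, so
    the full pipeline runs at desk scale without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    limma,
    stats,
    utils
Suggests:
    edgeR,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
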