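Package: persistqtl
Title: Linkage Mapping of Fungal Persistence from Pooled Barcode Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping quantitative trait loci that control the
    persistence of barcoded haploid yeast segregants in host organs.
    Implements the full inference chain from per-sample barcode read
    records to classified loci: UMI deduplication and Hamming-distance
    barcode counting, frequency-change persistence phenotypes with
    plate-growth residualization, broad-sense heritability from replicated
    barcodes with ANOVA-based sample filtering, vectorized forward-regression
    genome scans with permutation-derived significance thresholds and
    -log10(P)-drop confidence intervals, cross-sample locus consolidation,
    and classification of loci as general versus antagonistically
    pleiotropic with bootstrap effect intervals and allele-dose summaries.
    A synthetic-data generator simulates meiosis, organ-specific selection,
    recovery bottlenecks, and multinomial sequencing counts so the whole
    pipeline is testable end to end, and a two-state hidden Markov model
    corrects and imputes low-coverage genotype calls.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
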