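Package: divsweep
Title: Selective Sweep Scans, Nucleotide Fixation and Diversity Analysis for
    Multi-Population Resequencing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Windowed nucleotide-diversity statistics (theta-pi, Watterson's
    theta, Tajima's D), selective-sweep scans for two breeding transitions
    (a bottleneck-model scan contrasting wild and cultivated groups, and a
    population-branch-statistic scan isolating the elite lineage),
    identification of nucleotide-fixation loci with coding-effect
    classification, SNV rarefaction curves and site-frequency spectra,
    population structure by PCA and neighbor-joining with bootstrap support,
    and QTL-interval narrowing with gene-category enrichment. Includes a
    seeded three-population simulator with nested bottlenecks and injected
    sweeps for validation against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    vcfR,
    ape,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
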