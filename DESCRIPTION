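Package: bulkmap
Title: Bulked-Segregant Mapping of a Single Dominant Locus with Simulated
    F2/F3 Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for QTL-seq style bulked-segregant analysis (BSA) of a
    single dominant locus in a biparental F2 population: SNP-index,
    delta(SNP-index) and squared Euclidean distance (ED^2) statistics with
    sliding-window smoothing and significance thresholds, Mendelian
    segregation testing, regional two-point linkage estimation,
    recombinant-driven fine-mapping interval delimitation,
    diagnostic-marker panel concordance, coding-sequence consequence
    analysis and 2^-ddCt relative expression.  A seeded F2/F3 population
    and read-depth simulator generates every input the pipeline consumes,
    so the whole analysis runs end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    ggplot2,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    optparse,
    knitr
Config/testthat/edition: 3
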