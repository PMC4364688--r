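Package: InbredImpute
Title: Marker Imputation Benchmarking for Inbred Line Panels
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation-based benchmarking of genotype imputation in fully
    inbred diversity panels, modelled on elite wheat SNP-array data. Provides
    a founder-mosaic panel simulator with controllable linkage disequilibrium
    and allele-frequency spectrum, two masking designs (nested low-to-high
    array imputation and GBS-like random depletion), four imputation
    algorithms (allele-frequency baseline, iterative Random Forest,
    sliding-window haplotype matching, and a Li-Stephens haploid copying HMM),
    per-marker accuracy evaluation stratified by linkage disequilibrium and
    minor allele frequency, Rogers' distance diversity analysis with Mantel
    tests, RR-BLUP/GBLUP genomic prediction, and kinship-corrected
    mixed-model association scans with detection-frequency power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    ranger,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0),
    vcfR,
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
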