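Package: silkscan
Title: Windowed Selection Scans and Germplasm Comparison for Silkworm Resequencing Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Sliding-window nucleotide diversity (Pi), Pi-ratio and Fst selection
    scans with empirical outlier thresholds for multi-population SNP panels,
    plus outlier-region gene annotation, hypergeometric GO enrichment,
    neighbor-joining phylogeny from genotype distances, and trait-table
    comparison statistics. Includes a Balding-Nichols genotype simulator with
    designated high-differentiation windows so every stage of the pipeline can
    be exercised against a known ground truth, and an end-to-end scan driver
    that writes reproducible, manifest-stamped outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    GenomicRanges,
    graphics,
    grDevices,
    IRanges,
    jsonlite,
    S4Vectors,
    stats,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
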