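Package: phenomescape
Title: Genome-by-Phenome Landscapes from GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds interactive genome-by-phenome "landscapes" from per-trait
    GWAS summary-statistics files. Summary files for many phenotypes are
    harmonized once into a single long-format table; chromosomes are
    partitioned into base-pair segments (fixed-width bins, default 1 Mb, or
    LD-block intervals from a BED file); and per-segment, per-phenotype peak
    SNPs above a significance floor are selected for plotting as a 3D surface
    with a heatmap projection and user-selectable significance strata.
    Companion modules map peak SNPs to genes by windowed interval overlap,
    perform linkage-disequilibrium analytics from summary statistics alone
    (LD neighbours of a lead SNP, mutual LD across traits, linked-SNP
    proportion, and recursive LD thinning to expose buried independent
    signals), export regional summary statistics for colocalization tools,
    and generate fully synthetic multi-phenotype fixtures with planted
    ground truth for hermetic testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    IRanges,
    S4Vectors,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
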