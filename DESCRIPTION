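Package: olfzones
Title: Quantitative Mapping of Spatial Expression Zones in the Olfactory
    Epithelium
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying the spatial distribution of olfactory
    receptor gene expression from serial horizontal sections of the teleost
    olfactory rosette. Converts per-cell measurements into three normalized
    coordinates (laminar height, relative radius, organ height), summarizes
    per-gene distributions by empirical cumulative distribution functions
    and quartile descriptors, compares genes pairwise with two-sample
    Kolmogorov-Smirnov tests, and partitions genes into expression zones
    from the resulting indistinguishability graph. Includes a seeded
    generator of synthetic cup-shaped organs for validation at desk scale,
    and the curation filters used to accept bona fide members of a receptor
    gene family (gap-column stripping, allele collapsing, distributed
    sequence difference, genomic overlap and phylogenetic support filters).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    ape,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml,
    ggplot2,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
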