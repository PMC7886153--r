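Package: mitophylo
Title: Mitogenome Alignment Curation, Windowed Phylogenetic Signal and
    SuperTRI Supertree Support
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for mitochondrial phylogenomics at the whole-mitogenome
    scale: alignment curation (region masking, singleton-indel removal,
    transversion recoding, protein-coding-gene extraction), uncorrected
    pairwise distances with 1%-divergence haplotype dereplication and a 2%
    intraspecific screening report, codon-position base composition with
    AT3/CG3 strand skews and leave-one-out outlier flagging, circular
    half-overlapping genome windows, per-window neighbor-joining trees with
    bootstrap, SuperTRI-style aggregation of per-window bipartition support
    into a weighted matrix-representation-with-parsimony (MRP) matrix with
    bootstrap supertree support and node-signal classification, fossil
    calibration prior construction (uniform, normal, and offset lognormal
    with quantile-matched shape), and a seeded synthetic-data generator for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    stats,
    utils,
    tools,
    yaml
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
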