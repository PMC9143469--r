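Package: cypome
Title: Genome-Wide Cytochrome P450 Complement Mining, Nomenclature and
    Biosynthetic Gene Cluster Linkage
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for mining the cytochrome P450 complement (CYPome) of
    bacterial genomes from protein FASTA files, validating candidates with
    the conserved EXXR (K-helix) and CXG (heme-binding) motifs, assigning
    family and subfamily labels by percent identity against a reference
    panel of named P450s under the International P450 Nomenclature
    Committee thresholds (>40% family, >55% subfamily), profiling family
    presence/absence across genomes with hierarchical clustering, linking
    P450 genes to secondary metabolite biosynthetic gene cluster (smBGC)
    intervals, building neighbor-joining protein phylogenies, and
    computing CYPome summary statistics. Includes a fully specified
    synthetic-genome simulator with planted ground truth so the entire
    pipeline is testable without external databases, plus packaged
    transcriptions of published Salinispora CYPome tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    phangorn,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
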