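Package: ironcensus
Title: Census of Iron-Oxidation and Extracellular Electron Transfer
    Machinery in Genome Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Comparative-genomics pipeline for locating iron-oxidation and
    extracellular electron transfer (EET) machinery across a cohort of
    bacterial genomes. Scans proteomes for the CXXCH/CX3CH/CX4CH heme-binding
    motifs of c-type cytochromes, clusters multiheme cytochromes under a
    bidirectional-coverage criterion with greedy set-cover, classifies
    clusters against a labelled reference catalog, calls porin-cytochrome
    complexes (Cyc2, MtoAB, PCC3, Uet, Slit-type gene clusters) from gene
    colocalization, profiles metabolic marker genes with per-group
    prevalence summaries, computes reciprocal-best-hit AAI, gene-based ANI
    and 16S identity, and builds a concatenated ribosomal-protein
    neighbor-joining tree with bootstrap support. Ships a synthetic-cohort
    generator with planted truth tables so every stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    BiocGenerics,
    ape,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
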