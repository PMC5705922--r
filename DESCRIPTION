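Package: phagedepth
Title: Depth and Time Structure of Ocean Bacteriophage Assemblages from
    Assembled Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Post-assembly analysis of double-stranded DNA phage
    populations sampled across a stratified open-ocean water column.
    Implements viral contig curation (length filter, structural-gene
    requirement, cellular-contamination screen), homology classification
    of contigs against reference phage genomes and viromes by an
    average-amino-acid-identity majority rule, spatiotemporal abundance
    statistics (interquartile-mean coverage, relative abundance,
    depth-group binning, mean-normalized temporal variance), gene-catalog
    assemblage clustering (Bray-Curtis, average linkage), lysogeny
    indices from prophage and capsid marker coverage, per-genome marker
    copy numbers, and auxiliary-metabolic-gene candidate detection by
    colocalization with structural genes. Ships a seeded synthetic-data
    generator that emulates a 7-depth by 12-timepoint sampling design
    with depth-stratified phage populations, so the whole pipeline is
    testable without any sequence download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    vegan,
    ape,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
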