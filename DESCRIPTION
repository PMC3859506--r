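Package: aerobiome
Title: Whole-Genome-Shotgun Profiling of Low-Biomass Airborne Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for whole-genome-shotgun analysis of
    low-biomass airborne metagenomes sequenced after whole-genome
    amplification. Implements read quality control (artificial-replicate
    collapsing, DUST-style low-complexity filtering, repeat-coverage
    filtering), detection of phi29/MDA chimeric reads (internal-repeat
    search, similarity propagation, pairwise rearrangement-pattern
    classification and neighbourhood voting), kingdom-level taxonomic
    assignment from nucleotide and peptide homology searches,
    decomposition of the unclassified reads' GC-content distribution as a
    two-component mixture by symmetric Kullback-Leibler minimization, and
    gene-length/read-length-normalized KEGG ortholog and COG functional
    profiling with ordination. A synthetic-community simulator with full
    truth labels makes every stage testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
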