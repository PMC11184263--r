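Package: ctenokit
Title: Comparative Genomics Toolkit for Ctenophore Genome Assembly and
    Annotation Pipelines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reusable implementations of the bespoke computational stages
    used to assemble and analyse compact marine invertebrate genomes:
    in-silico mate-pair library generation for hybrid scaffolding,
    scaffold breaking at large assembly gaps, assembly summary statistics
    (N50, GC content, completeness percentages), rescue of gene models
    missed by ab initio predictors via orthogroup logic, consolidation of
    single-copy orthologs across clustering runs with gene-tree cherry
    and isoform rescue, six-frame catalytic-motif scanning with
    reciprocal-best-hit classification of chitinases, cross-species
    conserved differential-expression filtering, and macrosynteny-based
    chromosome assignment. A seeded synthetic-data module generates
    two-species genomes with known linkage structure, orthogroups with
    planted one-to-ones, gene trees with planted cherries, differential
    expression tables with planted conserved genes, and genomes with
    planted catalytic motifs, so that every stage is testable without
    large external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    ape,
    methods,
    phytools,
    rtracklayer,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
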