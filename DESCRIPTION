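Package: ccf1tx
Title: Haplotype-Aware Transcriptomics for (C57BL/6J x Collaborative Cross) F1 Mice
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A desk-scale pipeline for expression analysis of genetically
    diverse (C57BL/6J x Collaborative Cross) F1 mice. Reconstructs
    Collaborative Cross strain transcriptomes from the eight founder
    transcriptomes and haplotype mosaic files, combines them with the
    maternal C57BL/6J copy into diploid F1 references, quantifies
    transcript-allele abundance from reads by expectation-maximization over
    equivalence classes, and carries expression matrices through
    low-expression filtering, sequencing-PC covariate regression, Welch
    differential expression with Benjamini-Hochberg control, consensus
    signed weighted co-expression networks (biweight midcorrelation,
    topological overlap, quantile-scaled component-wise-minimum consensus,
    dynamic dendrogram module detection, eigengenes, kME pruning),
    Fisher-exact gene-set enrichment, gene-set eigengenes, and permutation
    module-preservation Z-summary statistics. Includes a fully seeded
    synthetic-data generator that emulates the breeding design (hemizygous
    5xFAD x CC crosses with 50 percent transgene carriers) and produces
    ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    jsonlite
Config/testthat/edition: 3
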