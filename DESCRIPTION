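Package: lncscape
Title: Genome-Wide lncRNA Identification and Functional Annotation
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A reusable pipeline for genome-wide identification and functional
    annotation of long non-coding RNAs (lncRNAs) from assembled transcript
    models. Assembled transcripts are classified against a reference
    annotation with cuffcompare-style class codes, cleaned of organelle,
    known-ncRNA and intronic contamination (the latter with a two-classifier
    machine-learning filter over assembly features), and stripped of
    coding-capable transcripts via similarity, length, coding-potential
    (ORF/Fickett) and domain filters. Surviving lncRNAs are annotated through
    tissue specificity (Tau/TSI), adjacent coding genes, and topological
    overlap (TOM) co-expression with gene-set enrichment; downstream tools
    mine the network for pathway-related lncRNAs, expression-pattern clusters,
    negatively correlated lncRNA-gene pairs and differentially expressed
    lncRNAs, scan lncRNA promoters for transcription-factor motifs with exact
    p-values, infer two-tier reciprocal-best-hit orthologs, and classify genes
    as lignin- versus flavonoid-pathway preferred. A synthetic-data module
    generates every input with planted ground truth so the whole pipeline is
    testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    BiocGenerics,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    SummarizedExperiment,
    rtracklayer,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    limma,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
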