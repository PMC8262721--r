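Package: coregmap
Title: Co-Regulation Networks and QTL Co-Mapping for Multi-Omic Systems
    Genetics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scriptable workflow for proteome- and transcriptome-wide
    systems genetics: pairwise co-regulation analysis of quantitative
    expression matrices (Pearson, Spearman or biweight midcorrelation
    with multiple-testing correction), annotation of correlated pairs
    against protein-complex and interaction references with enrichment
    and sensitivity testing, subcellular-localisation propagation and
    drug-target lookup, e/pQTL filtering with cis/trans classification
    and Sequence Ontology variant-impact annotation, SNP co-mapping of
    molecular and phenotypic traits, and assembly of typed multi-omic
    networks with LD-block or chromosome summarisation, exportable as
    GraphML, CSV and static figures. Includes a seeded synthetic-study
    generator with planted structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    tools,
    SummarizedExperiment,
    S4Vectors,
    igraph,
    ggplot2,
    jsonlite
Suggests:
    readxl,
    testthat (>= 3.0.0)
biocViews: Network, Proteomics, Transcriptomics, SystemsBiology,
    GeneExpression, SNP, GraphAndNetwork
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
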