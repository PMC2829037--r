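Package: linspec
Title: Identification and Characterization of Lineage-Specific Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies a focal proteome into evolutionarily conserved,
    clade-specific, and species-specific gene sets by staged homology
    filtering against taxon-tagged sequence databases (a desk-scale
    Smith-Waterman search backend with Karlin-Altschul E-values stands in
    for genome-scale BLAST, and tabular hit files can be ingested instead),
    then characterizes the sets: genic feature metrics, paralogous family
    construction from curated and alignment-derived protein domains,
    collinear gene-pair chaining into segmentally duplicated blocks,
    co-expression neighborhoods against a resampled null correlation
    threshold with GO term enrichment (Fisher exact tests and Storey
    q-values), cytosine methylation density in gene-relative regions,
    synonymous/non-synonymous SNP classification with per-gene densities
    and set-level ratios, and gene-level subcellular localization
    assignment from per-isoform predictions. A synthetic-data generator
    produces every pipeline input with planted ground truth so the whole
    analysis is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    methods,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
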