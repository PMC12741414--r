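Package: chemorep
Title: Chemosensory Receptor Repertoire Screening and Genomic Distribution Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for annotating chemosensory G-protein-coupled receptor gene
    repertoires (OR, V1R, V2R, CaSR and related families) from homology-search
    and domain-hit tables, classifying them into bootstrap-supported clades on
    a gene tree, relating phylogenetic to genomic distance to quantify tandem
    clustering, comparing landmark-anchored microsynteny across species, and
    calling organ-specific expression from TPM matrices. Includes a
    ground-truthed simulator of gene-family expansion by tandem duplication
    with occasional dispersal, so every pipeline stage can be exercised and
    validated without genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    mclust,
    withr,
    ggplot2
Config/testthat/edition: 3
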