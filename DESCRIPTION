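Package: cazyreg
Title: Inducer-Response Transcriptomics of Plant-Cell-Wall-Degrading Enzymes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative analysis pipeline connecting chemically defined
    enzyme inducers to the regulation of plant-cell-wall-degrading enzymes in
    filamentous fungi. Provides per-inducer differential expression against a
    glucose reference (Welch t-tests on log2 intensities), GO-term count
    matrices with correlation-based descriptor ranking, self-organizing-map
    seeded k-means and hierarchical clustering, per-pathway regulation
    fractions over a genome-scale metabolic network, secretome and CAZy
    regulation tables, a guilt-by-association co-expression network, and a
    metabolite-to-reaction-to-gene association table for candidate
    transcription-factor-binding metabolites. A synthetic-data module with
    planted ground truth supports end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    mclust,
    pheatmap,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
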