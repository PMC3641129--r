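Package: coan
Title: Protein Complex Prediction on Ontology Augmented Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts protein complexes from a protein-protein interaction
    (PPI) network jointly with Gene Ontology (GO) slim annotations. The PPI
    graph is augmented with one dummy vertex per GO slim connected to the
    proteins it annotates; a delay-damped random walk on the augmented graph
    yields a unified closeness measure that fuses topological proximity with
    annotation similarity. Complexes are predicted by ranking maximal cliques
    by unified-distance density, selecting disjoint seed cliques by overlap
    pruning, and expanding each seed with neighbouring proteins whose
    connectivity score clears a threshold. Includes complex-prediction
    evaluation metrics (neighbourhood-affinity matching, precision/recall/F1,
    Sn/PPV/accuracy), readers and writers for edge-list, annotation (TSV and
    GAF 2.x) and complex-catalogue formats, and a synthetic planted-complex
    benchmark generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
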