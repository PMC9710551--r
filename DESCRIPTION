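Package: savanno
Title: Pathogenicity Annotation of Protein Single Amino Acid Variants from
    Sequence and Function Embeddings
Version: 0.1.0
Authors@R:
    person("Alex", "Moretti", email = "alex.moretti@example.org",
           role = c("aut", "cre"))
Description: Classifies human protein single amino acid variants (SAVs) as
    pathogenic (P/LP) or benign (B/LB) from embedding-based encodings of the
    wild-type sequence, the variant sequence and the protein's Gene Ontology
    annotation. Provides dataset curation from tabular variant catalogues,
    homology-aware cross-validation partitioning by connected-component
    clustering of sequence-similarity graphs, pluggable per-residue embedding
    backends with a deterministic mock backend, leaf-filtered GO term-vector
    averaging, a PCA plus RBF-kernel support vector machine classifier with
    isotonic probability calibration and an integer reliability index, full
    evaluation machinery (accuracy, precision, recall, F1, ROC-AUC, MCC with
    per-fold statistics), a synthetic-fixture generator with controllable
    class signal, and a command-line interface tying the stages together.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
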