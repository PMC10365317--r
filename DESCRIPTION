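Package: rbphost
Title: Phage Host Genus Prediction from Receptor-Binding Protein Embeddings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for predicting the bacterial host genus of tailed
    phages from their receptor-binding proteins (RBPs). Mines annotated RBPs
    from GenBank flat files or annotated FASTA using inclusion/exclusion
    annotation rules, an undetermined-residue filter and an interquartile-range
    length filter; converts protein sequences into fixed-length vectors by
    mean-pooling per-residue embeddings from a pluggable embedder, with
    non-overlapping chunking for length-limited embedders; standardizes host
    names to genus and resolves polyvalent phages; builds a multiclass design
    restricted to the most frequent host genera with an "others" rejection
    class appended to the test set; trains a class-weighted random forest with
    the associated hyperparameter search; and evaluates predictions under a
    confidence-threshold rejection scheme with class-size-weighted precision,
    recall, specificity and F1. Includes a synthetic-corpus generator so the
    whole pipeline is testable without external data or model downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ranger,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
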