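Package: neorank
Title: Multi-Encoder Ensemble Prediction of Neoantigen Immunogenicity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting the immunogenicity of mutant peptide-HLA
    pairs and prioritizing neoantigen candidates. Implements curation of
    8-11-mer peptide-HLA training tables, k-mer tokenization with TF-IDF,
    one-hot and deterministic contextual embeddings, z-score scaling, SMOTE
    class rebalancing confined to training folds, three compact neural
    submodels (two fully connected networks and a parallel-kernel
    convolutional network) trained with Adam and cross-entropy, a rank-level
    consensus ensemble over their ranked outputs, mutant-peptide enumeration
    from missense variants, an immunogenicity feature registry,
    Top-N capture and AUC evaluation, dataset characterization statistics,
    ELISpot response classification, in-silico cell-free DNA read mixing,
    and a synthetic-data generator that emulates curated neoantigen
    training sets so the whole pipeline runs offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    jsonlite,
    generics,
    stats,
    utils,
    Biostrings,
    randomForest,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC,
    vcfR
Config/testthat/edition: 3
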