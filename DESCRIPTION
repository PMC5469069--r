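Package: strandbind
Title: Sequence-Based Classification of Single- Versus Double-Stranded
    DNA-Binding Proteins
Version: 0.1.0
Authors@R:
    person("strandbind", "developers", email = "strandbind@example.org",
           role = c("aut", "cre"))
Description: Classifies DNA-binding proteins as single-stranded DNA binders
    (SSBs) or double-stranded DNA binders (DSBs) from amino-acid sequence
    alone.  Implements four feature-encoding families (square-root overall
    amino-acid composition, gapped dipeptide compositions at intervals 0-2,
    split-amino-acid-partitioned AAindex physicochemical encodings, and
    split-amino-acid-partitioned PSSM profile encodings), balanced training
    via majority-class down-sampling, built-in random-forest and support
    vector machine classifiers, a majority-voting ensemble across feature
    families, stratified cross-validation with a full metric suite
    (ACC/SN/SP/MCC/F1/AUC), a label-permutation baseline, and descriptive
    class-contrast statistics.  Includes a synthetic-data generator so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
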