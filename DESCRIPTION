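Package: intclass
Title: Associative Classification of Gene-Expression Profiles by
    Discretized Expression Intervals
Version: 1.0.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Supervised classification of gene-expression matrices built on
    class-association rules over discretized expression intervals. Genes are
    screened with a per-gene Welch t-test (or Kolmogorov-Smirnov test), each
    kept gene is partitioned into intervals by entropy-based supervised
    splitting (ID3), equal-width binning, a ternary up/normal/down baseline,
    or a pass-through mode; maximal frequent itemsets of (gene, interval)
    items are mined per phenotype class with a MAFIA-style depth-first bitmap
    miner and turned into association rules; unknown samples are assigned to
    the class whose rules they maximally satisfy. Includes leave-one-out
    cross-validation with ROC/AUC, greedy leave-one-gene-out rule pruning, a
    one-versus-all multi-class wrapper, a synthetic-data generator with
    planted interval structure, and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
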