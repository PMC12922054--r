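Package: cashgame
Title: Coalitional Microarray Games and Shapley-Value Gene Prioritization
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Two-condition transcriptomic analysis via cooperative game
    theory. Expression values are Boolean-encoded as over- or
    under-expression relative to control-group statistics, each sample's
    flagged genes form a winning coalition, and per-gene Shapley values
    summarise cooperative relevance within each condition. Genes are
    prioritised by the absolute difference in Shapley values (ADSV)
    between conditions, with significance assessed by the CASh
    label-resampling procedure and a two-criterion selection rule.
    Includes a synthetic-data generator with planted cooperative signal,
    a bundled toy dataset, a brute-force classical Shapley oracle for
    validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
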