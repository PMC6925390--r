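Package: sleepdep
Title: Detecting Sleep-Deprived Authors of Micro-Blog Posts from Wearable Sleep Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Labels timestamped micro-blog posts as written while sleep deprived
    or sleep sufficient using a piecewise-linear tiredness model driven by
    minute-level wearable sleep episodes, and trains a gated recurrent unit
    (GRU) classifier on a word-embedding feature tensor (CBOW word vectors
    plus sentiment polarity, subjectivity and hour of posting) to predict that
    label from the text alone.  Includes a synthetic-world generator producing
    sleep schedules and state-dependent post streams with a tunable textual
    effect size, so the full pipeline is testable end to end, plus a small
    command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
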