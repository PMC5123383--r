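Package: fuzzydea
Title: Possibilistic Differential Expression Analysis for RNA-Seq with
    Multireads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Differential expression analysis for RNA-Seq experiments in
    which a substantial fraction of reads map to more than one gene
    (multireads). Instead of discarding ambiguous reads or resolving them
    with a probabilistic model, each gene's read count is represented as a
    trapezoidal fuzzy number built from graded mapping possibilities, fold
    change is propagated through the extension principle, and every gene
    receives three possibility degrees - over-, same- and under-expression
    - by sup-min intersection of its joint count relation with
    expression-dependent membership surfaces. Includes parsers for
    BLAST-style tabular and SAM alignments, median-of-ratios
    normalization, replicate merging rules, a synthetic-experiment
    generator with known ground truth, and a command-line runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    Rsamtools,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    DESeq2,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
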