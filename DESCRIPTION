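Package: chillmir
Title: Small RNA, Degradome and qPCR Analysis of Chilling-Responsive miRNAs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for identifying chilling-responsive
    microRNAs and their cleavage targets from two-library (treated versus
    untreated) plant small RNA sequencing experiments. Implements adapter
    trimming, length and junk filtering, collapsing to unique tags,
    contaminant classification and library composition reports; conserved
    miRNA identification by anchored mismatch matching against a known mature
    set; novel miRNA discovery by precursor excision, hairpin folding and the
    minimal folding free energy index (MFEI) filter; two-library differential
    expression with chi-square and Fisher exact tests under a dual
    p-value/fold-change threshold; degradome (PARE) cleavage-site calling
    with duplex penalty scoring, t-plots, tags-per-billion normalization and
    category 0-4 classification; and 2^-ddCt quantification of qPCR Ct
    tables. A synthetic-data generator with a planted-truth manifest supports
    end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    stringr,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils,
    withr,
    Rcpp,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
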