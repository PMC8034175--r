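Package: gementropy
Title: Entropic Complexity Measures for Medical Coding Transitions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the difficulty of migrating between two medical
    coding systems from their general equivalence mappings (GEM-style
    crosswalks). For every source code it computes two Shannon-entropy
    measures in bits: the alphabet entropy H(A), summed over character
    positions of the candidate target codes, and the representation
    entropy H(B) = log2(v), where v counts the valid stand-alone and
    combination (scenario / choice-list) representations of the source
    code; the log2(m) uncertainty-rate baseline is included for
    comparison. Measures are z-normalized, optionally weighted by
    empirical code frequencies, summarized, aggregated into ranked
    clinical classes with Kendall tau rank agreement, and screened for
    outlier concepts whose descriptions can be explored through a word
    co-occurrence network with eigenvector centrality. A seeded
    synthetic-crosswalk generator with recorded ground truth supports
    testing without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
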