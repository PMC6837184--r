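Package: cohsi
Title: Conservation of Hartley-Shannon Information for Discrete Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the information-theoretic analysis of discrete systems
    built from tokens (proteins from amino acids, software functions from
    language tokens, musical compositions from notes). Provides exact
    arbitrary-precision counting of strings with a fixed unique alphabet and
    the resulting Hartley-Shannon information content, numerical solution of
    the implicit heterogeneous length-distribution equation (sharp unimodal
    peak with power-law tail) and of the homogeneous rank equation (Zipf's law
    with a drooping tail), readers that reduce FASTA proteomes, token streams
    and note-event tables to component tables of (length, unique alphabet),
    empirical distribution machinery (ccdf, exponential binning, rank
    recategorization, dual-alphabet tables), and a discrete power-law tail
    assessment battery (maximum-likelihood exponent, KS-based xmin selection,
    Monte Carlo bootstrap plausibility). Seeded synthetic generators supply
    desk-scale inputs with known ground truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
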