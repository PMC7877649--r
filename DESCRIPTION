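Package: scriptsurp
Title: Script-Knowledge Event Chains, Event Surprisal, and Ordinal Rating Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the predictability of everyday events given
    extralinguistic (script) context. Reads crowd-sourced event-sequence
    description (ESD) corpora, normalizes raw descriptions to canonical
    verb-noun event labels via machine-readable lexicons, fits event-level
    bigram language models, computes event surprisal in bits, extracts
    maximum-likelihood event chains, and derives predictable/unpredictable
    stimulus specifications for acceptability experiments. Includes
    synthetic generators (probabilistic script graphs with lexical noise;
    Likert rating tables from a known ordinal mixed model) and a
    cumulative link mixed model (Laplace approximation, crossed random
    effects) with likelihood-ratio backward selection for analyzing
    7-point acceptability ratings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    xml2,
    stats,
    utils,
    jsonlite
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
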