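Package: pathtag
Title: Recognition of Named Biological Pathway Mentions in Text
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Finds mentions of named biological pathways (e.g. "MAPK
    signalling pathway") in biomedical text by combining soft dictionary
    matching against a pathway-name dictionary with keyword-anchored,
    part-of-speech-based rules gated on gene/protein mentions. The soft
    matcher scores candidate windows with the SoftTFIDF hybrid similarity
    (TFIDF token weighting combined with Jaro-Winkler character similarity)
    under dual score thresholds; rule and dictionary annotations are merged
    into a final set. Includes strict and lenient span-level
    precision/recall/F1 evaluation against gold-standard corpora, readers
    and writers for tab-separated dictionaries and standoff annotations, a
    reader for inline-XML gold corpora, dictionary lexical profiling, a
    deterministic synthetic corpus generator emulating common pathway-name
    variations, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    xml2,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
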