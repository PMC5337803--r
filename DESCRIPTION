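Package: aspectsent
Title: Ontology-Driven Aspect-Level Sentiment Analysis for Health Social Media
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Lexicon-based aspect-level sentiment analysis for short
    social-media texts about diabetes. Normalizes tweets (mention/URL/hashtag
    stripping, abbreviation expansion, pluggable spell correction), tokenizes,
    sentence-splits, POS-tags and lemmatizes them with a deterministic
    rule-based backend, detects domain aspects by longest-match lookup against
    a gazetteer built from a flat term list or an OWL ontology's labels and
    synonyms, extracts N-gram before/after/around context windows around each
    aspect, aggregates SentiWordNet-format prior-polarity scores over the
    window, and assigns positive/negative/neutral labels by a strict-inequality
    rule. Includes span-level precision/recall/F evaluation with macro and
    micro averaging, a method-by-window-size sweep, a seeded synthetic corpus
    generator with gold labels for end-to-end testing, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
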