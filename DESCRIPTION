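Package: ashn
Title: Interpretable Attribute-Based Detection of Postpartum Depression Risk from Social-Media Posts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens users for postpartum-depression risk from their collections of
    short social-media posts with an attribute selection hybrid network: four
    psychologically motivated attribute encoders (part-of-speech style, sentiment
    polarity, DSM-5 symptom-keyword similarity, ruminative repetition), softmax
    attribute fusion, and post-level attention over a user's posts, trained end to
    end with a built-in reverse-mode automatic-differentiation engine. Also provides
    the cohort cleaning pipeline (character cleaning, post-length and token-length
    filters, minimum-post user filter, screening-score group assignment), linguistic
    feature extraction (tokenizer, lightweight part-of-speech tagger over a fixed
    48-tag inventory, three-way sentiment lexicon, nine-category symptom lexicon,
    vocabulary construction, word-frequency tables), evaluation metrics with
    attention-based interpretation reports, a bidirectional recurrent baseline, and
    a seeded synthetic-corpus generator for end-to-end testing without private data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
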