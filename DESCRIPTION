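Package: triggersense
Title: Word-Type Disambiguation for Biomedical Event Trigger Detection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects and classifies biomedical event trigger words by treating
    each frequent, ambiguous word type (lemma plus coarse part of speech) as a
    separate word sense disambiguation problem. Provides readers and writers
    for BioNLP 2009-style standoff annotation with token, dependency and MeSH
    sidecar layers, selection of disambiguation targets by training frequency
    and class skew, four collocational feature families, a nearest-prototype
    vector space classifier with a majority-class baseline, per-feature class
    entropy profiling that predicts where disambiguation helps, micro-averaged
    evaluation with paired approximate randomization significance tests,
    export of cross-validated predictions as a feature column for sequence
    taggers, and a seeded synthetic corpus generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
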