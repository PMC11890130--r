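Package: medfactcheck
Title: Evidence-Based Fact-Checking of Online Health Information
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An automated evidence-based fact-checking pipeline for online
    health information. Web pages are reduced to sentences, each sentence is
    assigned one of four thematic labels (neutral, semiology, epidemiology,
    management) by a trainable classifier, MeSH terms and keyphrases are
    extracted per thematic category and assembled into boolean PubMed
    queries, related open-access systematic reviews and meta-analyses are
    retrieved (live via NCBI E-utilities or from an offline fixture store),
    and web-page sentences are matched against same-category literature
    sentences by cosine or Jaccard similarity at a configurable threshold to
    produce a per-page credibility report. Ships deterministic backends
    (keyword classifier, dictionary MeSH matcher, term-frequency keyphrase
    ranker, feature-hashing sentence embedder) and a synthetic-data
    generator so the whole pipeline runs and tests offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    xml2,
    nnet,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
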