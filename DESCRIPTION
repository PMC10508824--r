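Package: genesetlm
Title: Gene Set Function Discovery with Large Language Models
Version: 0.1.0
Authors@R: person("genesetlm", "maintainers", email = "maintainers@genesetlm.dev", role = c("aut", "cre"))
Description: A pipeline for interpreting gene sets with large language
    models and for evaluating those interpretations against curated
    knowledge. Builds an engineered seven-section prompt that asks an LLM
    for a concise biological-process name, an analysis essay and a
    self-confidence score; parses and caches responses from pluggable
    backends; calibrates proposed names against the Gene Ontology name
    corpus by semantic-similarity percentile; benchmarks LLM confidence
    with contaminated (50/50 mix) and fully random gene sets; provides a
    native hypergeometric/Benjamini-Hochberg/Jaccard functional-enrichment
    baseline; and attaches PubMed citations to essay statements via a
    five-step keyword-extraction and support-judgment loop. Ships
    deterministic scripted LLM, embedding and PubMed fixtures so the whole
    pipeline runs offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
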