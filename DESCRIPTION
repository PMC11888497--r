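Package: polyglotdx
Title: Multilingual Benchmarking of LLM Differential Diagnosis for Rare Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, fully offline pipeline for benchmarking large
    language models on rare-disease differential diagnosis across languages.
    Reads structured case vignettes (a GA4GH Phenopacket subset), renders
    templated narrative prompts in nine languages using multilingual Human
    Phenotype Ontology translations, queries a pluggable text-generation
    backend (deterministic mock and recorded backends included), grounds
    free-text candidate diagnoses to a Mondo-like disease ontology with
    genetic-subtype equivalence, scores ranked differentials at Top-1/3/10,
    and aggregates per-language counts, frequencies and a Kruskal-Wallis
    cross-language comparison. Ships seeded synthetic generators for every
    fixture so all stages are testable without network access.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringi,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
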