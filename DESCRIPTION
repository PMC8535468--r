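Package: clinconcept
Title: Rule-Based Extraction and Classification of Clinical Concepts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts candidate clinical concept phrases from unstructured
    narrative notes, resolves them against a Metathesaurus-style knowledge
    base (concepts, semantic types, semantic groups) with exact and
    approximate dictionary matching, and classifies each phrase as a medical
    problem, treatment, or test by majority voting over dictionary-mapped
    semantic types with positional tie-breaking. Includes readers and
    writers for the i2b2-2010 '.con' annotation format, span-level
    precision/recall/F1 and sensitivity scoring with macro averages, and a
    seeded generator for an offline fixture knowledge base and synthetic
    annotated corpora.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
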