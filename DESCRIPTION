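Package: protsem
Title: Semantic Translation of Laboratory Protocols into Machine-Amenable Workflows
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Translates plain-text biomedical laboratory protocols into a
    structured, semantically typed representation. A bundled catalog of
    experimental actions (incubate, store, aliquot, ...) defines, for each
    action, the descriptors (temperature, period, biochemical entity,
    equipment, condition, ...) that are essential for reproducibility and
    those that are optional. Rule-based text processing identifies actions
    and descriptor values (with unit-ontology identifiers), expands
    lab-specific abbreviations, resolves defaults such as overnight = 16 h,
    and reports missing essential information. Structured protocols compile
    to place/transition Petri nets whose simulation checks executability;
    nets export to PNML, Graphviz DOT and JSON. A seeded generator produces
    synthetic protocols with ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    stringr,
    tibble,
    utils,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
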