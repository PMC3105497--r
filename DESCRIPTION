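Package: flowsynth
Title: Semantics-Based Synthesis and Verification of Bioinformatics Service Workflows
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Taxonomy-backed domain models for collections of command-line
    bioinformatics services (EMBOSS-style tools described by symbolic input
    and output types), automatic domain construction from EMBOSS ACD tool
    descriptors linked to an OBO ontology such as EDAM, temporal-logic
    constrained synthesis of service sequences over a type-accumulation
    state space (loose specification), and linear-time model checking of
    workflow process graphs with per-node verdicts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
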