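Package: fcakb
Title: Patient Similarity Knowledge Bases via Formal Concept Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds hierarchical knowledge bases of clinical cases with formal
    concept analysis (FCA). Clinical attribute tables (demonstrated on
    colorectal-cancer prognostic factors: age, differentiation, histology,
    TNM staging, tumor markers, lymph-node ratio) are one-hot binarized into a
    formal context; the complete concept lattice is enumerated with the
    NextClosure algorithm and its Hasse (covering) structure computed; and
    ranked similar concepts are retrieved for a new patient with a weighted
    extent/intent set-overlap similarity. Includes a seeded synthetic-cohort
    generator matching published marginal frequencies, Burmeister CXT and
    binary-CSV context I/O, DOT/CSV/JSON lattice export, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
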