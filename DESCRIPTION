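Package: demesr
Title: Read, Resolve, Validate and Convert Demes Demographic Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for the Demes standard for describing demographic models
    in population genetics. Reads the concise human-written YAML/JSON form,
    resolves hierarchical defaults and size/time inheritance into the fully
    explicit machine form, validates models and reports machine-readable
    diagnostics, simplifies resolved models back to a minimal document,
    converts to and from the ms coalescent simulator's command-line dialect,
    generates random valid models for property-based testing, and renders
    models as SVG tube diagrams.
License: MIT
Encoding: UTF-8
Imports:
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
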