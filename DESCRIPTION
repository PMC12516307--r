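Package: denofor
Title: Standardized Methodology Annotation for De Novo Gene Studies
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the DeNoFo standardized annotation format, which
    documents the methodology of de novo gene detection studies (input data
    sources, evolutionary age inference, homology filtering, non-coding
    homolog evidence, wet-lab verification and hyperlinks) in a single
    machine-validated record. Provides a validating data model with
    controlled vocabularies, the human-readable .dngf JSON dialect, a
    compact carrier-safe shortcode embeddable in FASTA headers and GFF3
    attribute columns, converters between these carriers, a field-by-field
    comparator for two studies, a questionnaire state machine for building
    annotations interactively, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    utils,
    stats
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    rtracklayer
Config/testthat/edition: 3
RoxygenNote: 7.3.3
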