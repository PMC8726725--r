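Package: gblica
Title: Linked Independent Component Analysis of Brain Networks and Gut Microbiota
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint decomposition of resting-state brain-network connectivity
    maps and gut-microbiota relative abundance by linked independent component
    analysis (LICA): all modality-specific factorizations share one
    subject-loading matrix, so each component expresses coupled variation
    across modalities. Includes dual regression to derive subject-specific
    network z-maps from template resting-state networks, genus-level
    prevalence filtering and relative-abundance normalization of 16S count
    tables, per-component modality contribution fractions with the
    accompanying component-selection and quality-control rules, a synthetic
    cohort generator with known ground truth for validation, and a
    config-driven end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    biomformat,
    jsonlite,
    yaml,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
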