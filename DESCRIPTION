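Package: ChimeraZoo
Title: Doddington-Zoo-Constrained Chimeric Multimodal Biometric Datasets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
        role = c("aut", "cre"))
Description: Builds chimeric (virtual) multimodal biometric datasets from
    per-modality feature tables under Doddington-Zoo menagerie constraints
    (sheep, goats, lambs), with full seed-based reproducibility of every
    stochastic stage. Evaluates unimodal and fused verification performance
    (feature-level concatenation; sum, min and product score-level fusion)
    via decidability, DET curves and the equal error rate, across
    intra-session and inter-session scenarios, and aggregates a repeated
    seeded experimental protocol with pairwise comparisons against the
    best-performing method. Includes a synthetic multi-session feature
    generator with controllable menagerie structure so the whole protocol
    is testable without external biometric data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, jsonlite, S4Vectors, SummarizedExperiment
Suggests: testthat (>= 3.0.0), withr, knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
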