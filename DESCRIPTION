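Package: topoperturb
Title: Comparative Analysis of Drug-Induced 3D Genome Perturbation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify how a chromatin-perturbing drug reshapes
    higher-order genome organization from binned Hi-C contact maps and
    companion genomic tracks. Implements iterative matrix correction,
    observed/expected transforms, Armatus-score TAD segmentation with a
    TAD border-strength statistic, A/B compartment annotation with saddle
    plots, contact-probability scaling curves, a domain-conditioned distal
    contact caller with persistence classification, a percent-of-intersection
    peak persistence rule, gene-desert annotation, and single-particle FRET
    proximity-ratio mixture analysis. A synthetic-data generator with
    recorded ground truth makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    IRanges,
    S4Vectors,
    BiocGenerics,
    jsonlite,
    yaml,
    minpack.lm
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
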