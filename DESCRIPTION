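Package: clonescape
Title: Single-Cell Dissection of Multiple Myeloma Clonal Evolution
Version: 0.1.0
Authors@R: person("clonescape", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A tested, reusable pipeline for the single-cell analysis of
    multiple myeloma clonal evolution: cell and gene quality control, malignant
    plasma-cell immunophenotype gating, per-cluster marker detection by
    Wilcoxon rank-sum test, rank-based (Kolmogorov-Smirnov-style)
    single-sample gene-signature scoring and an expression stemness index, a
    three-detector consensus framework for ligand-receptor intercellular
    communication including a hypergeometric test against degree-preserving
    randomized ligand-receptor networks, malignant-origin dominance scoring
    and four-class typing, self-organizing-map analysis of marker-gene
    contributions to patient heterogeneity, a principal-component intratumor
    diversity score, and tumor-mutational-burden, substitution-spectrum and
    shared-variant analysis at bulk and subclone level. A synthetic-data
    module generates count matrices and variant tables with the statistical
    structure every stage assumes, so the whole pipeline is testable without
    any external download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    tools,
    jsonlite
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
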