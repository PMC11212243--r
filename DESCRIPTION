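Package: netrecur
Title: Rare-Variant Recurrence and Network-Propagation Gene Prioritization
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Prioritizes candidate disease genes from an annotated cohort
    rare-variant table without a matched control cohort. Variants are
    reduced to unusually frequent variants (UFVs): rare, damaging,
    protein-altering variants whose cohort allele frequency exceeds a
    fold threshold over their reference-population frequency, or which
    are absent from the reference panel. Genes are scored by UFV
    recurrence and by confidence-weighted network propagation calibrated
    against an empirical null ensemble that preserves each patient's
    mutation count while reassigning mutations to uniformly random
    genes. Downstream modules provide hypergeometric gene-set
    enrichment with Benjamini-Hochberg control, diagnostic-panel
    cumulative cohort recovery versus the Hardy-Weinberg expectation in
    a general-population control cohort, cell-type expression-percentile
    comparison by Wilcoxon rank-sum tests, and a fully synthetic
    cohort/network/gene-set/expression generator for end-to-end
    validation against planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    fgsea
Config/testthat/edition: 3
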