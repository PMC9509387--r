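Package: cortexmeth
Title: Cell-Type-Aware EWAS of Cortical DNA Methylation and Neuropathology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for epigenome-wide association analysis of bulk cortical DNA
    methylation against ordinal neuropathology measures, with reference-based
    cell-type deconvolution from sorted-nuclei methylation profiles. Includes
    matrix-level quality control (detection-p filtering, principal-component
    outlier exclusion, quantile normalization), constrained least-squares
    estimation of NeuN+/SOX10+/double-negative nuclei proportions, cross-region
    linear mixed-model EWAS with donor random intercepts and joint
    multi-measure likelihood-ratio tests, empirical-null bias/inflation
    adjustment of test statistics, fixed-effects inverse-variance-weighted
    meta-analysis, and direction-concordance statistics between bulk and
    purified nuclei-fraction analyses. A synthetic-cohort generator emulating
    three-cell-type mixtures across two cortical regions with correlated
    ordinal pathology provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    lme4,
    limma,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    metafor,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
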