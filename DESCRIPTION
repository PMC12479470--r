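Package: prgskit
Title: Pathway-Responsive Gene Set Construction and Drug-Resistance Enrichment Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds pathway-responsive gene sets (PRGS) from compendia of pathway
    perturbation experiments, splits drug-response cohorts into sensitive and
    resistant groups from area-under-curve (AUC) chemosensitivity profiles, and
    tests pathways for association with resistance using three enrichment
    statistics: a weighted Kolmogorov-Smirnov running-sum (GSEA-like) score with
    a gene-set permutation null, a hypergeometric over-representation test, and
    a rank test whose null is the Bates distribution (mean of independent
    uniforms on [-1, 1]). Includes the normalization strategies the framework
    compares (rank-based inverse-normal, signed logarithmic, quantile), a
    synthetic-data generator with planted ground truth for end-to-end
    validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, optparse
Suggests: testthat (>= 3.0.0), limma, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
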