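Package: phosphoscreen
Title: Phosphoproteomic Biomarker Discovery for Treatment Response
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Differential phosphopeptide analysis between treatment
    responders and nonresponders, kinase-set enrichment analysis (KSEA)
    from phospho-motif annotations, immunohistochemistry H-score biomarker
    evaluation by upper-quartile dichotomization, and quantitative
    pull-down interactor enrichment. Includes Monte-Carlo
    Mann-Whitney-Wilcoxon permutation testing with Benjamini-Hochberg
    control, the classic (unweighted) running-sum enrichment statistic
    with permutation-based normalized enrichment scores and false
    discovery rates, and seeded synthetic-data generators emulating
    label-free phosphoproteomic, IHC cohort and affinity-purification
    data so every stage is testable without access to raw trial data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    fgsea
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
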