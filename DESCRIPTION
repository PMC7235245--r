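Package: apith
Title: Average Pairwise Intratumor Heterogeneity from Multi-Region Tumor Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Quantifies intratumor heterogeneity (ITH) from multi-region
    tumor sampling of somatic copy number alterations (SCNAs) and DNA
    methylation. Provides an average pairwise ITH index (APITH) whose
    expectation does not depend on the number of samples taken per tumor,
    together with a U-statistic variance model and inverse-variance weights
    for weighted Cox proportional-hazards association with clinical
    outcomes. Includes B-allele-frequency based copy-number segmentation
    with log-R-ratio segment classification, tumor-purity adjustment of
    methylation beta values, CpG island methylator phenotype calling,
    candidate driver event detection, minimum-evolution tumor phylogenies
    from consensus genetic plus epigenetic distances, and a synthetic
    multi-region tumor cohort generator with known clonal ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    ape,
    phangorn
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
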