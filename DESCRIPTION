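Package: dualtissue
Title: Comparative Two-Tissue Neonatal Methylome Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for comparing epigenome-wide association analyses across
    two surrogate neonatal tissues profiled on methylation arrays. Maps CpGs
    with inter-individual variability, scans variable CpGs against cis-SNPs
    (per-chromosome min-p methylation QTL scan with a genome-wide Bonferroni
    call) and against a panel of prenatal factors, accounts for cross-tissue
    overlap of variable, genotype-associated and factor-associated CpGs, and
    clusters surrogate-tissue methylomes against sequencing-based reference
    methylomes. Includes empirical-Bayes chip adjustment on M-values,
    reference-based cell-type deconvolution by constrained least squares,
    residual-PCA surrogate variables, and a seeded paired-tissue cohort
    simulator with a ground-truth manifest so every stage is verifiable at
    desk scale.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    vcfR,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    sva,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
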