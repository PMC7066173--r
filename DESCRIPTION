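Package: organoidkit
Title: Analysis Toolkit for Patient-Derived Kidney-Cancer Organoid Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational pipeline for characterising patient-derived
    kidney-tumour organoid biobanks: greedy mutational-signature refitting
    with forced clock-like signatures and cosine-similarity stopping rules,
    single-cell RNA-seq quality control with formula-defined cell-cycle-gene
    exclusion, Wilcoxon cluster-marker detection with Bonferroni correction
    and majority-vote cell typing, somatic-variant hard filtering, and
    four-parameter logistic dose-response analysis (IC50/AUC) of organoid
    drug screens. Includes seeded synthetic-data generators emulating the
    statistical structure of each input, plus TSV/MTX/VCF/CSV readers and a
    command-line entry point.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Matrix,
    pracma,
    minpack.lm,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
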