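Package: candgene
Title: Candidate-Gene Case-Control Association Testing and Genetic Risk
    Scores for Fatty Liver Disease
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for candidate-gene resequencing
    case-control studies of non-alcoholic fatty liver disease (NAFLD):
    post-caller variant quality filtering on VCF records, consensus
    deleteriousness scoring across five in-silico predictors, per-gene
    carrier-burden enrichment, per-SNP association under genotypic,
    dominant and recessive penetrance models with Woolf odds-ratio
    intervals, covariate-adjusted logistic modelling with forward-Wald
    selection, bootstrap p-value adjustment, a 4-SNP weighted genetic
    risk score with tertile analysis, and an analytic power calculator
    for one-stage genetic association designs.  Ships a synthetic cohort
    generator emulating the statistical structure of a two-group
    ultrasound-defined NAFLD study (HWE genotypes, logistic disease
    model, correlated metabolic covariates) for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
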