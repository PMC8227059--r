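Package: hybridgp
Title: Genomic Prediction for Structured Testcross Hybrid Populations
    across Environments
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis toolkit for genomic prediction of
    testcross hybrid performance in structured breeding populations.
    Simulates founder inbreds, backcross (BC1F3), doubled-haploid, and
    F4:5 populations by explicit meiosis on a genetic map, testcrosses
    them to a common tester, and generates multi-environment yield
    trials with controlled variance components.  Provides SNP quality
    control and hybrid additive/dominance genotype coding, principal
    component and similarity analyses of population structure,
    mixed-model trial analysis (BLUEs, ANOVA variance dissection,
    entry-mean heritability), additive and dominance genomic
    relationship matrices, GBLUP with REML or Gibbs solvers,
    single-environment, across-environment and genotype-by-environment
    prediction models, and the within-population, one-to-one,
    three-to-one, CV1 and CV2 evaluation schemes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    lme4,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    VariantAnnotation,
    SummarizedExperiment,
    GenomeInfoDb,
    BiocGenerics
Config/testthat/edition: 3
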