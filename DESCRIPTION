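Package: saltgp
Title: Genomic Selection for Salinity Tolerance in Rice
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for genomic prediction of salt-stress
    tolerance in japonica rice panels: SNP quality control and
    linkage-disequilibrium redundancy pruning, genomic kernels (linear
    GBLUP kernel and Gaussian RKHS kernel with posterior-mode bandwidth
    estimation), Gibbs samplers for single- and multi-environment
    genotype-by-condition mixed models, CV1 cross-validation of predictive
    ability with Fisher-Z analysis of variance, split-plot adjusted means
    and stress-response indices, representative validation-subset
    selection, population-structure summaries, and a synthetic-data
    generator with known truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    lme4,
    car,
    vcfR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
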