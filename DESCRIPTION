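Package: tau17q
Title: H1/H2 Haplotype and Subhaplotype Analysis at the 17q21.31 MAPT Locus
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for case-control analysis of the chromosome 17q21.31
    inversion polymorphism containing MAPT. Reads tag-SNV genotypes from VCF,
    assigns H1/H2 diplotypes and SNV-defined subhaplotypes via a configurable
    nomenclature table, and computes haplotype frequencies, Hardy-Weinberg
    exact tests, allelic and covariate-adjusted logistic association,
    age-at-onset contrasts, additive-model power and required sample size,
    and Gini-importance rankings of subhaplotypes from an extremely
    randomized tree ensemble. Includes a synthetic cohort simulator emitting
    phased VCF plus sample metadata for end-to-end testing and method
    calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    vcfR,
    yaml,
    jsonlite,
    ranger
Suggests:
    testthat (>= 3.0.0),
    optparse,
    ggplot2,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
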