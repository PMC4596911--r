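Package: famscore
Title: Genotype-Based Score Tests for Association in Multiplex-Case and
    Control Family Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Score tests for genetic association when cases are sampled from
    multiplex families and compared with unrelated controls. The variance of
    the score is adjusted for relatedness through pedigree-derived genotype
    correlation matrices (additive, recessive and dominant codings, autosomal
    and X-linked markers), imputed genotypes enter through posterior dosages
    with an information-loss correction and the post-analysis efficiency
    measure R2_T, and phenotypes of un-genotyped relatives can be folded into
    the test as kinship-weighted family-history weights. A simulator for
    ascertained nuclear-family case-control datasets (affected-sib-pair
    schemes, logistic disease model with a shared family effect) supports
    empirical type-I-error and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    optparse,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
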