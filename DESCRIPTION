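Package: cherryhap
Title: Pedigree-Based QTL and SNP Haplotype Analysis for Sweet Cherry
    Breeding Germplasm
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for pedigree-based quantitative trait locus (QTL) and
    SNP haplotype analysis in clonally propagated fruit-crop breeding
    germplasm, modelled on multi-parental sweet cherry populations.
    Provides a gene-dropping simulator (phased founder haplotypes,
    Haldane recombination, two-year fruit cracking and firmness
    phenotypes with planted haplotype effects), multi-year BLUPs as
    deviations from the model intercept, an iterative fixed-effects
    genome scan with BIC cofactor selection and linkage-disequilibrium
    exclusion, per-SNP variance explained and genomic heritability,
    Bayes-factor evidence classes and QTL stability consensus,
    primary-SNP-guided haplotype classification with functional effect
    assignment, and identity-by-descent haplotype tracking through the
    pedigree to terminal ancestors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
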