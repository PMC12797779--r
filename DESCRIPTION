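Package: popkit
Title: Forensic Population-Genetic Analysis of Biallelic Ancestry-Informative InDel Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the forensic and population-genetic characterisation of
    biallelic ancestry-informative insertion/deletion (AIM-InDel) marker panels.
    Reads labelled diploid genotypes from PLINK text ped/map pairs or dosage
    CSV tables; computes allele frequencies, exact Hardy-Weinberg tests,
    permutation tests of linkage disequilibrium, and the standard forensic
    parameter suite (Ho, He, PIC, match probability, powers of discrimination
    and exclusion, with panel-level cumulative values); simulates relative
    pairs under identity-by-descent kinship models and evaluates
    likelihood-ratio threshold sensitivities; measures population
    differentiation (F_ST, Nei's D_A, Rosenberg informativeness for
    assignment) and builds ordinations (PCA with cos2, classical MDS) and
    neighbor-joining trees; trains an RBF-kernel support vector machine for
    biogeographic-ancestry classification with a shuffled-label noise
    robustness protocol; and generates structured synthetic genotype panels
    under a hierarchical Balding-Nichols model so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    e1071,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    phangorn,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
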