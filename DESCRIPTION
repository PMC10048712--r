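Package: cranioprofile
Title: Physical and Molecular Biological Profiling of Unidentified Crania
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Dual physical and molecular biological profiling of unidentified
    human crania. Implements reference-anchored craniometric ancestry
    classification with Mahalanobis distances and posterior probabilities,
    Gower principal-coordinates analysis of inter-cranium distances,
    optimized summed scored attribute (OSSA) scoring and a naive-Bayes
    morphoscopic ancestry classifier, a conditional trait-equation framework
    for morphological sex estimation, molecular sex calling from X/Y
    chromosome alignment counts (the Ry statistic), genotype principal
    component analysis with least-squares projection of pseudo-haploid
    samples, haplogroup label parsing and frequency summarization, and a
    cross-method concordance audit. Ships synthetic-data generators
    (multivariate-normal craniometric panels, ordinal trait tables,
    Balding-Nichols genotype matrices, binomial read counts) so the whole
    pipeline is testable without restricted skeletal or genomic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    MASS,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
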