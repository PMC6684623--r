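Package: alkylseg
Title: Segregation Analysis of Cannabinoid Alkyl Side-Chain Chemotypes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to study the inheritance of cannabinoid alkyl side-chain
    and ring-type composition in Cannabis crosses. Converts per-plant LC-MS
    cannabinoid quantifications into propyl/pentyl (F_C3/F_C5) and
    dicyclic/tricyclic (F_dicyclic/F_tricyclic) chemotype fractions with
    decarboxylation correction and replicate averaging, demarcates multimodal
    fraction distributions into ordered chemotype categories using Gaussian
    kernel density estimation with a Sheather-Jones solve-the-equation
    bandwidth and baseline peak integration, and tests observed category
    counts against monogenic, digenic and epistatic segregation models by
    Pearson chi-squared goodness-of-fit, including analyses conditioned on
    the codominant THCAS/CBDAS synthase locus genotype and Bartlett variance
    homogeneity tests from summary statistics. A configurable F2 cross
    simulator with two-point linkage and selectable gene-action models
    generates synthetic study populations for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
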