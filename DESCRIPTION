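Package: famlmm
Title: Comparing Strategies for Family Structure in Marker-Wise Association
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for evaluating how marker-wise association scans should
    cope with family structure. Implements a family-structured phenotype
    simulator under a linear mixed model with kinship covariance, pedigree
    kinship construction (recursive coefficients, exchangeable sibship
    blocks, PLINK .fam input), a from-scratch spectral REML / generalized
    least squares association engine with three covariance options
    (one representative per family, full kinship random effect, or complete
    independence), and a comparison harness that ranks markers, forms top-k
    sets, computes three-way Venn overlaps, truth recovery and false
    discovery rates across replicate runs, and evaluates a hybrid strategy
    that intersects the independence and representative hits.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
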