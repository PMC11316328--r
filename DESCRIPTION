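Package: svgp
Title: Genomic Prediction with Structural-Variant Kernels, Bayesian
    Regression and Deep Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genomic prediction studies that partition genome-wide
    variation into SNPs and five structural-variant classes (MITE-DTX,
    RLX-RIX, DEL, DUP, INV). Builds class-specific VanRaden, dominance and
    additive-by-additive epistatic relationship kernels; fits multi-kernel
    RKHS and BayesC spike-and-slab regressions with from-scratch Gibbs
    samplers (Gaussian and probit-augmented binary responses); performs
    fold-internal GWAS marker selection and LD-based tagging of structural
    variants by SNPs; trains multilayer perceptrons, 1-D convolutional
    networks and six-branch multi-input networks with a successive-halving
    hyperparameter search; and runs leakage-safe 10-fold and
    across-population cross-validation experiments. A synthetic-data
    generator with known ground truth (population structure, class-specific
    causal variance shares, SV-SNP linkage, liability-threshold binary
    traits) makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    jsonlite,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
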