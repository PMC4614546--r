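Package: reopair
Title: Purity-Robust Gene-Pair Prognostic Signatures for Mixed-Tissue
    Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to study how the cellular composition of macro-dissected
    tumor tissue distorts differential expression and prognostic signatures,
    and to build signatures that are robust to it. Implements rank-products
    differential expression with permutation-based false discovery control,
    hypergeometric overlap and binomial direction-consistency statistics for
    DEG lists, purity-correlation summaries, a Fisher's exact screen for
    reversed within-sample gene-pair orderings, and a Cox-selected
    binomial-vote gene-pair risk classifier evaluated by Kaplan-Meier,
    log-rank, concordance and covariate-adjusted Cox regression. A synthetic
    data module simulates matched epithelial/stromal profiles, purity-weighted
    tissue mixtures and coupled relapse-free survival with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    survival,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
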