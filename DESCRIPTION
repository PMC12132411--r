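Package: bmdd
Title: Bimodal Dirichlet Imputation for Zero-Inflated Microbiome Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Probabilistic imputation of zero-inflated microbiome count
    tables. Each taxon's relative abundance is given a bimodal Dirichlet
    prior (a two-point mixture over the Dirichlet shape, selected by a
    per-taxon Bernoulli indicator), fitted by a coordinate-ascent
    mean-field variational EM algorithm. The fitted model yields
    posterior-mean compositions for single imputation and posterior
    samples for multiple imputation. Includes a generative simulator
    (correctly specified and misspecified settings with inter-taxon
    correlation), a fifteen-metric composition-recovery evaluation
    suite with pseudocount baselines, and a multiple-imputation
    differential abundance harness with compositional bias correction
    and Rubin's-rule pooling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr,
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
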