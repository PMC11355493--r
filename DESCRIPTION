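Package: rvbmix
Title: Bayesian Mixture-Model Rare-Variant Gene Association
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Gene-based association testing for ultra-rare variants from
    case-control minor-allele counts. Per-variant Bayes factors contrast a
    risk model, in which the relative risk is drawn from a class-specific
    Gamma prior, against a binomial null split of carriers between cases and
    controls. Variant-level evidence is combined into gene Bayes factors
    under a two-level mixture over risk genes and risk variants; the
    proportion of risk genes and the per-class proportions of risk variants
    are estimated by EM, candidate genes are nominated by Bayesian FDR, and
    nominated lists are characterised by gene-set overlap and fold-change
    enrichment statistics. Includes a synthetic case-control count generator
    with known ground truth for end-to-end calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
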