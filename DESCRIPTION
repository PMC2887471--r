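Package: varprio
Title: Variance Prioritization for Quantitative-Trait Interaction Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection of SNP-covariate and SNP-SNP interaction effects on
    quantitative traits by variance prioritization: SNPs are first screened
    for inequality of trait variance across genotype classes with Levene's
    (mean-centered) test, and the prioritized subset is then tested for
    interaction by linear regression with a Bonferroni correction scaled by
    the screening threshold. Includes the closed-form variance algebra of the
    underlying interaction model, a Hardy-Weinberg simulator for gene-by-
    environment and gene-by-gene designs, Monte-Carlo power experiments with
    an analytic noncentral-F cross-check, genotype quality control (call
    rate, sample missingness, exact Hardy-Weinberg test, minor allele
    frequency), and a genome-wide Levene scan with quantile-quantile output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    car,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
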