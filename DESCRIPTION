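Package: phescan
Title: Bayesian Phenome-Wide Scan for Causal Query Variants Accounting for
    Linkage Disequilibrium
Version: 0.1.0
Authors@R:
    person("phescan", "developers", email = "phescan@example.org",
           role = c("aut", "cre"))
Description: Tests whether a variant with known causal effect on a primary
    trait (the query variant) is also causal for each of many query traits,
    using regional GWAS summary statistics. For each region three hypotheses
    are weighed: no causal variant (Hn), a causal variant other than the query
    variant (Ha, linkage-disequilibrium confounding) and the query variant
    itself causal (Hc). Evidence enters through Wakefield approximate Bayes
    factors under a single-causal-variant assumption, or through a minimal
    sum-of-single-effects (SuSiE) decomposition on z-scores plus an LD matrix
    when multiple causal variants are plausible. Priors over the hypothesis
    space can be fixed or learned across all tested regions by a hierarchical
    Metropolis-Hastings model, optionally modulated by a per-trait covariate
    such as genetic correlation with the primary trait. A simulation module
    generates benchmark datasets with known truth, and a comparator implements
    conventional p-value-threshold PheWAS (Benjamini-Hochberg, Bonferroni).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
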