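Package: gutcog
Title: Mixed-Effects Random Forest Analysis of Gut Microbiome and Cognition
Version: 0.1.0
Authors@R: person("gutcog", "Maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: Tools for relating longitudinal gut metagenomic profiles to
    cognitive performance in older adults. Reads MetaPhlAn-style taxonomic
    and HUMAnN-style functional abundance tables together with per-visit
    clinical metadata; derives composite memory and executive-function
    z-scores standardized within visit; classifies subjects into healthy
    control, mild cognitive impairment, and dementia groups; fits
    random-intercept linear mixed models for alpha diversity; and predicts
    cognitive outcomes with a mixed-effects random forest (subject random
    intercepts estimated by EM alternation with a bagged regression forest),
    Boruta all-relevant feature selection, cross-validated permutation
    variable importance with empirical-null p-values, Spearman/FDR feature
    annotation, and KEGG-ortholog enrichment. Includes a synthetic
    longitudinal cohort generator with planted effects for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    lme4,
    jsonlite,
    optparse,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
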