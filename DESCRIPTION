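Package: gutmaz
Title: Gut Microbiota Maturity, Dysbiosis Statistics and Mediation Analysis
Version: 0.1.0
Authors@R:
    person("Min", "Developer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies gut microbiota maturation and dysbiosis from 16S rRNA
    OTU count tables. Implements averaged rarefaction, alpha and beta
    diversity with PERMANOVA and Mantel tests, random-forest regression of
    chronological age on genus abundances with the microbiota-for-age Z
    score (MAZ), an OTU-table-to-image encoder feeding a small convolutional
    age classifier with median-of-top-3 aggregation, covariate-adjusted
    per-feature association models, Spearman co-occurrence networks,
    tenfold cross-validated random-forest classification, and a bootstrap
    product-of-coefficients mediation model linking disease, a microbial
    mediator score, and comorbidity. Ships an age-structured
    Dirichlet-multinomial cohort simulator with known maturation
    trajectories and mediation structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
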