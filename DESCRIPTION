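Package: nsdohmix
Title: Bayesian Multivariate Bernoulli Mixture Profiles of Neighbourhood
    Social Determinants of Health
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives latent neighbourhood profiles of social determinants of
    health from binary census-tract indicators with a fully Bayesian
    multivariate Bernoulli mixture model. The number of profiles is learned
    from the data by a collapsed allocation sampler with an overfitted
    component bound and a truncated Poisson prior on the number of
    components, accelerated by Metropolis-coupled (parallel-tempered) chains.
    Posterior draws are post-processed for label switching with the
    equivalence-classes-representatives (ECR) algorithm, tracts are assigned
    to their maximum-probability profile, and profile membership is related
    to a binary care outcome by a Bayesian logistic regression. Includes
    median-dichotomization preprocessing of American Community Survey style
    indicator tables, a Yost-type principal-component socioeconomic index as
    a one-dimensional comparator, and synthetic-data generators with known
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite,
    rlang
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
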