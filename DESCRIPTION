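Package: symbiocor
Title: Genetic Correlations Between Partner Fitness Components in
    Factorial Symbiosis Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing balanced genotype-by-genotype-by-environment
    (GxGxE) greenhouse experiments on the legume-rhizobium mutualism, in which
    plant fitness (fruit count) and symbiont fitness (nodule count) are scored
    on every plant.  Provides balanced three-way fixed-effects ANOVA of each
    fitness component, per-environment one-way MANOVA cross-product matrices
    over host-genotype x rhizobium-mix associations, method-of-moments
    estimates of the broad-sense genetic and environmental covariance matrices,
    the derived genetic (r_G) and environmental (r_E) correlations with
    delete-one-association jackknife standard errors, genotypic-mean summaries
    with major-axis fits, and a calibrated synthetic-data generator emulating a
    6 genotype x 2 mix (+ uninoculated control) x 2 soil x 5 replicate design
    with carvacrol-treated versus control soil.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    jsonlite,
    stats,
    utils
Suggests:
    car,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
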