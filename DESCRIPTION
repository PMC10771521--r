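Package: aesthetwin
Title: Twin-Design Analysis of Inter-Individual Differences in Aesthetic Evaluations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to study why people differ in their visual aesthetic
    evaluations. Provides quality control for repeated image-rating data,
    the three aesthetic phenotypes (pairwise agreement, taste-typicality,
    evaluation-bias), crossed random-effect variance partitioning of
    ratings, and full-information maximum-likelihood Classical Twin Design
    models: saturated, univariate ACE/ADE/AE/CE/E and multivariate
    direct-symmetric ACE, with likelihood-based confidence intervals,
    heritability, bivariate heritability and genetic and environmental
    correlations. A twin-structured rating simulator with known
    additive-genetic, shared-environment, dominance and unique-environment
    ground truth makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    lme4,
    car,
    emmeans,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
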