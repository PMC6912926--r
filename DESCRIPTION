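Package: finsexer
Title: Automated Phenotypic Sexing of Zebrafish from Lateral Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies the phenotypic sex of adult zebrafish from lateral
    RGB photographs using two complementary machine-learning routes: a
    Gaussian-kernel support vector machine on CIE L*a*b* color histograms of
    the caudal fin, and a small residual convolutional network on the whole
    body image. Downstream statistics quantify classifier-versus-truth
    agreement (phi coefficient), model sex ratios with a logit-link Bernoulli
    GLM and back-transformed least-squares means, derive a z-transformed
    fin-color intensity from the SVM decision values, and relate that
    intensity to body weight and length by polynomial analysis of covariance
    with backward elimination, studentized-residual outlier screening and
    Tukey-Kramer adjusted least-squares means. A synthetic cohort generator
    renders fish-like images with configurable sexual dichromatism, treatment
    attenuation and size-color coupling so the whole pipeline is testable
    without photographs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    emmeans,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tiff,
    withr,
    yaml
Config/testthat/edition: 3
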