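Package: frechet3
Title: Maximum Likelihood and Lindley-Approximate Bayesian Inference for the Three-Parameter Frechet Distribution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Density, distribution, quantile and random generation for the
    three-parameter Frechet (extreme value type-II) distribution, together
    with constrained quasi-Newton maximum likelihood fitting, the observed
    Fisher information, and approximate Bayes estimators obtained by
    Lindley's expansion of the posterior under LINEX and general entropy
    loss functions with noninformative and gamma priors. Includes a Monte
    Carlo engine for bias/MSE comparison of the estimators and a
    Kolmogorov-Smirnov goodness-of-fit workflow for right-skewed survival
    data, with a bundled head-and-neck-cancer survival data set.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, graphics, utils
Suggests: testthat (>= 3.0.0), pracma, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
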