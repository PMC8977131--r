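Package: driftlearn
Title: Diffusion Modelling of Perceptual Learning with Neurochemical and
    Connectivity Associations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing how training changes perceptual
    decision processes. Implements Wiener first-passage-time machinery
    (density, choice probability, trial simulation) with across-trial
    variability in drift, start point and nondecision time; quantile-based
    multinomial fitting of block-constrained drift diffusion models with
    BIC model selection and quantile-probability diagnostics; behavioral
    trial-table screening and learning deltas; post-processing of
    quantified MRS metabolite concentrations (quality filtering, CSF
    tissue correction, reference switching); ROI time-series functional
    connectivity (soft ICA cleanup, discrete-cosine high-pass, group
    overlap masks, first eigenvariate, Fisher-z correlations); the
    association statistics linking brain measures to behavioral change
    (robust bisquare regression with standardized effect sizes,
    dependent-correlation comparison, paired tests, mixed 2x2 ANOVA);
    and a synthetic cohort generator so the whole chain runs without any
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    MASS,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
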