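Package: olfclust
Title: Unsupervised Pattern Discovery in Olfactory Subtest Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Density-based featurization and emergent self-organizing map (ESOM)
    clustering of three-subtest olfactory data (odor threshold, discrimination,
    identification). Provides a synthetic cohort generator with a planted latent
    profile structure, sex-specific linear age correction and TDI diagnosis
    labelling, Pareto density estimation with Gaussian-mixture featurization into
    Bayesian posterior probabilities, training of a toroidal ESOM with U-matrix,
    P-matrix and U*-matrix landscapes, watershed-style cluster extraction, and
    cluster-versus-etiology association statistics (chi-squared, relative
    difference overrepresentation, Spearman correlations by subgroup).
License: GPL (>= 3)
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
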