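Package: mirstrat
Title: Prognostic Patient Stratification by MicroRNA-Gene Expression Association
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens all microRNA-gene pairs in matched expression profiles for
    subgroup-restricted negative correlation. For each pair a greedy search,
    restarted from random patient triples, grows a subgroup in which the microRNA
    and its candidate target are significantly anti-correlated while the
    complement shows no association; pairs whose subgroup split also stratifies
    overall survival (log-rank test, Bonferroni family-wise control) are retained,
    abundance-driven artifacts are filtered by rank-sum balance tests, and
    binding-site support from target-prediction tools can be joined in. Includes
    survival-label permutation false-discovery assessment, initialization
    sensitivity analysis, covariate balance checks, and a synthetic data
    generator with planted subgroups for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    survival,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
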