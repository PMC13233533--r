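Package: xdomcf
Title: Cross-Domain Aesthetic Preference Modeling via Collaborative Filtering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the cross-domain consistency of aesthetic preferences as a
    user-based collaborative filtering problem. Participants are encoded by
    inter-subject similarity of their ratings within a stimulus domain; sparse
    nonnegative aggregation weights are learned with a SLIM-style elastic-net
    solver in a source domain and transferred to predict held-out responses in
    a target domain. Includes second-order (inter-domain) similarity analysis,
    Fisher-z correlation aggregation, weight-shuffling permutation tests,
    cohort-size ablation, gender-stratified conditions, a ridge-regression
    feature baseline with closed-form leave-one-out cross-validation, and a
    seeded latent-trait cohort generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
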