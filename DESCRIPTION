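Package: kdtriage
Title: Two-Step Triage Classification of Kawasaki Disease Versus Febrile Controls
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a two-step diagnostic triage algorithm that
    differentiates Kawasaki disease (KD) from other pediatric febrile
    controls (FC) using routine clinical and laboratory data. Step one
    scores patients with a Fisher linear discriminant over illness days,
    the five principal clinical criteria and a laboratory panel, with two
    score thresholds calibrated to positive- and negative-predictive-value
    targets so that patients between the thresholds are called
    indeterminate rather than forced into a class. Step two rescues
    indeterminate patients with random forests trained separately within
    strata defined by the number of principal criteria. The package also
    provides k-nearest-neighbour imputation of missing laboratory values,
    a calibrated synthetic cohort generator for end-to-end testing, the
    three-way evaluation protocol (sensitivity, specificity, PPV, NPV and
    indeterminate rates with their exact denominators), stratified
    performance reports, exact nonparametric tests, cohort file I/O with
    schema validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    randomForest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS
Config/testthat/edition: 3
RoxygenNote: 7.3.3
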