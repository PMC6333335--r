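Package: chdstrat
Title: Decision-Analytic Optimization of Risk-Score Testing and Statin
    Treatment in Coronary Heart Disease Prevention
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Health-economic decision model for targeting a traditional
    clinical risk score (TRS) and a polygenic genetic risk score (GRS) to
    guide statin therapy for primary prevention of coronary heart disease
    (CHD) events over a 10-year horizon. Values the four end states of the
    testing-and-treatment decision tree (discounted costs, QALYs, net
    monetary benefit), updates a patient's 10-year event risk from binned
    test results by Bayes' rule, solves ten population testing strategies by
    backward induction over the decision tree, and runs probabilistic,
    one-way, and two-way sensitivity analyses with re-optimization at every
    parameter draw. Includes a synthetic cohort generator with binormal
    score distributions so the full pipeline is testable without access to
    the original register data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
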