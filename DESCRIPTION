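Package: sibbn
Type: Package
Title: Bayesian Belief Networks Linking Sanitary Inspections to Household Drinking Water Quality
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to build and estimate discrete Bayesian belief networks that
    relate sanitary-inspection observations at the point of collection and the
    point of use to Escherichia coli detection in household drinking water.
    Provides exact inference by variable elimination, expectation-maximisation
    learning of conditional probability tables from survey records with
    block-missing source data, index-scored intermediate risk nodes with
    deterministic (locked) tables, k-fold cross-validated AUC assessment with
    Greiner's qualitative accuracy classes, node-by-node predictive inference
    (delta-P sweeps), what-if scenario simulation, and a synthetic household
    survey generator emulating a rural water-quality study.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: jsonlite, stats, utils
Suggests: testthat (>= 3.0.0), pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
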