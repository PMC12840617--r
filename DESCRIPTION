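Package: peptiforge
Title: Discovery and Characterization of DPP-IV Inhibitory Peptides from
    Precursor Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An integrated in silico pipeline for discovering dipeptidyl
    peptidase-IV (DPP-IV) inhibitory peptides from food proteins:
    rule-based proteolysis with missed-cleavage enumeration and sequential
    gastrointestinal (gastric/intestinal) digestion, the bioactive-fragment
    frequency statistic A = a/N against a motif database, 27-component
    pseudo amino acid composition (PseAAC) featurization, a grid-searched
    cross-validation harness over tree-ensemble classifiers with the five
    standard binary metrics and feature importances, multi-criteria
    peptidomics screening (abundance, length, bioactivity score, and the
    DPP-IV position-2 Pro/Ala substrate rule), and enzyme-inhibition
    kinetics: global Michaelis-Menten/inhibition-model fitting with AICc
    model discrimination, Lineweaver-Burk diagnostics, closed-form Ki,
    logistic IC50 fitting, and the associated assay arithmetic. Synthetic
    data generators for every input make all stages testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    minpack.lm,
    randomForest,
    xgboost,
    seqinr,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
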