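Package: raads14
Title: Scoring, Validation and Simulation for the RAADS-14 Screen
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the RAADS-14 Screen, a 14-item self-report screening
    questionnaire for autism spectrum disorder in adult psychiatric
    populations, and for short-form Likert instruments generally. Provides
    instrument definitions with reverse-coded items, subscales and screening
    cut-offs; record-validity filters (straight-lining, excess missingness);
    a psychometric kernel (Mann-Whitney U with tie-corrected normal
    approximation, rank-based effect sizes, empirical ROC curves and the
    U-AUC identity, cut-off selection under a sensitivity constraint,
    Cronbach's alpha, corrected item-total correlations, discrimination
    indices, principal-axis factor analysis); the three-phase item-reduction
    pipeline used to derive short forms from a larger item bank; and a
    calibrated graded-response simulator that generates synthetic diagnostic
    cohorts for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
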