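Package: pharmvig
Title: Quasi-Experimental Digital Pharmacovigilance from Longitudinal Text Timelines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A tested pipeline for discovering medication side-effect language
    from longitudinal social-media style text timelines. Implements drug-lexicon
    mention matching, personal medication-intake classification, pretreatment
    covariate construction, propensity-score estimation by L2-penalized
    iteratively reweighted least squares with equal-width stratification,
    relative treatment effect (RTE) estimation per stratum, most/least-improved
    cohort selection, contrastive keyword extraction with a sparse additive
    generative (SAGE) language model under a self-tuned regularization prior,
    and normalized n-gram co-occurrence prevalence for named side effects.
    Includes a synthetic timeline generator with confounded treatment
    assignment, heterogeneous post-treatment improvement and planted
    side-effect keywords, so every stage can be validated by recovery of
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
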