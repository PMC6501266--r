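Package: eegdecode
Title: Intersubject EEG Decoding with Kernel SVM Sensitivity Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decoding of binary stimulus superclasses (animate versus
    inanimate) from epoched multichannel EEG under leave-one-subject-out
    cross-validation. Provides single-trial and category-averaged
    (pseudotrial) RBF-kernel support vector machine classifiers with
    exposed dual coefficients, nested, debiased double-holdout and
    oracle cross-validation schemes, analytic kernel-derivative
    sensitivity maps over channel-by-time features, NPAIRS split-half
    effect-size scaling of ERP difference and sensitivity maps,
    Bonferroni-corrected paired t-test maps, permutation tests of
    decoding accuracy, and a synthetic event-related paradigm simulator
    that plants a recoverable animacy effect so every stage can be
    exercised without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    kernlab,
    jsonlite,
    yaml,
    methods,
    stats,
    utils,
    tools
Suggests:
    e1071,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
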