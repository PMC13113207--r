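Package: mortexplain
Title: Interpretability Toolkit for Automated Underlying-Cause-of-Death Coding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to interrogate classifiers that select the underlying cause of
    death (UCOD) from ICD-10 coded death certificates. Provides confidence
    calibration diagnostics (expected and maximum calibration error, reliability
    diagrams) with post-hoc temperature scaling; token-level Variance-of-Gradients
    instance-difficulty scoring across training checkpoints with out-of-distribution
    flagging for rare codes; Integrated Gradients word attribution; and ICD-10
    chapter- and category-stratified performance reporting. Ships a synthetic
    certificate generator with a rule-derived ground truth, a reverse-coding step
    that renders certificates as sentences, and a small differentiable text
    classifier so the whole workflow runs end to end without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
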