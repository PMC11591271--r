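Package: hemotrace
Title: Arterial-Waveform Tracking of Hemorrhage and Resuscitation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for tracking blood loss and
    whole-blood resuscitation from the arterial pressure waveform. Generates
    controlled swine hemorrhage/resuscitation cohorts and stepwise lower-body
    negative pressure (LBNP) protocols; resamples, lowpass-filters, detrends
    and segments arterial waveforms into beats with five pulse landmarks;
    expands each beat into a bank of more than 4200 named features; computes
    ground-truth blood-loss metrics (BLVM, PEBL, HemArea) and the compensatory
    reserve measurement (CRM); ranks features by a minimum-redundancy
    maximum-relevance criterion and trains least-squares gradient-boosted
    regression trees under leave-one-subject-group-out cross-validation; and
    scores models with percentile-sweep ROC curves, hemorrhage detection
    times, and resuscitation-responsiveness statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    pracma,
    rpart,
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
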