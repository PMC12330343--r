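Package: photowd
Title: Fiber Photometry and Behavioral Analysis of Nicotine Withdrawal
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of dual-channel fiber photometry recordings
    and associated behavioral assays in a nicotine-withdrawal paradigm:
    isosbestic-corrected dF/F with double-exponential photobleaching removal,
    median/MAD robust z-scoring, prominence-based calcium and dopamine
    transient detection with pre/post-injection window comparisons, peri-event
    alignment and response classification around novel-object interactions,
    ROC discriminability between saline and mecamylamine sessions, and
    conditioned place preference, open field, and somatic-sign scoring.
    Includes a synthetic dual-channel recording and behavior-track generator
    with ground truth for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
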