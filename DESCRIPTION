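Package: healstage
Title: Transcriptional Staging of Muscle Injury Healing from Time-Course RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies bulk RNA-seq samples to post-injury healing stages from
    replicate-level FPKM expression tables. Implements replicate quality filtering
    and aggregation, per-time-point fold-change profiling, two time point signature
    classifiers (count-based and fold-change-weighted), distance-weighted one-vs-one
    support vector machine voting, nearest-sample classification in principal
    component space, and pathway-level activation scoring, together with a synthetic
    time-course generator that emulates the statistical structure of a muscle
    freeze-injury study design for testing and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    e1071,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
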