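Package: socialseq
Title: Trajectory-Based Analysis of Social Behavior Sequences in Grouped Mice
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing dyadic social behavior in mixed-sex groups of
    tracked mice. Detects opposite-sex interaction bouts from fitted pose
    ellipses, extracts aggression-triggered behavioral sequences and their
    latency and duration statistics, classifies three-step (bait-and-switch)
    sequences, and evaluates state dependence with circular statistics,
    permutation nulls, difference indices, and decision-tree and multiclass
    margin decoders with size-matched and time-randomized controls. Includes
    a multi-agent arena simulator that plants ground-truth events and
    interaction episodes so every stage of the pipeline can be validated
    without video data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    rpart,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
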