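Package: transfeat
Title: Transition-Based Physiological Feature Selection for Emotional Stress Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Extracts 39 physiological features from electrocardiogram (ECG),
    blood volume pulse (BVP) and galvanic skin response (GSR) recordings over
    sliding windows of a three-emotion elicitation session, and selects
    stress-sensitive feature subsets by testing paired differences across
    emotional state transitions. Includes a synthetic cohort simulator with
    planted physiological ground truth, discrete-state (Kruskal-Wallis) and
    PCA baselines, a Pearson-correlation redundancy filter, and a four
    classifier cross-validation harness for emotion and stress tasks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    pracma,
    jsonlite,
    stats,
    utils,
    class,
    rpart,
    randomForest,
    e1071
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
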