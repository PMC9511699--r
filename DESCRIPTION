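Package: frameindep
Title: Testing Statistical Independence of Sequential Image Frames for
    Machine Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to decide whether sequential grayscale image frames
    acquired from the same subject (for example B-mode ultrasound video
    clips) are independent enough to be used as separate machine-learning
    training instances. Region-of-interest grayscale distributions are
    compared with the Jensen-Shannon divergence, sampled within cases at
    every time shift and between cases, and a one-sided equivalence
    (noninferiority) t-test with margin delta = 0.05 * M1 decides per group
    whether within-case frames diverge as much as frames from different
    cases. Includes gray-level run-length texture features (GLNU, RLNU),
    first-order histogram features, divergence-versus-shift curves with
    autocorrelation period estimation (respiratory motion), leave-one-out
    logistic-regression and random-forest evaluation with ROC/AUC, and a
    seeded synthetic speckle-video phantom generator for end-to-end
    validation without in-vivo data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
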