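Package: shockadvice
Title: Shock Advice Algorithm for Shockable-Rhythm Detection in Single-Channel ECG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects shockable rhythms (ventricular fibrillation and ventricular
    tachycardia) in 8-second single-channel ECG segments, the decision problem of
    the shock advice algorithm in automated external defibrillators. Segments are
    filtered (5-tap moving average, 1 Hz high-pass, 30 Hz Butterworth low-pass),
    decomposed by variational mode decomposition with center frequencies pinned
    at 2, 3.5, 5, 6.5 and 8 Hz into shockable- and non-shockable-oriented
    channels, passed through a parameterized 1-D convolutional network whose
    first fully connected layer yields a 100-dimensional deep feature vector,
    and classified by a boosting ensemble. Includes a synthetic ECG generator,
    record-wise cross-validation with grid-search model selection, and
    sensitivity/specificity/balanced-error-rate reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    e1071,
    class,
    randomForest,
    rpart,
    glmnet,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
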