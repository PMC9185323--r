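Package: gfevote
Title: Multi-Perspective Soft-Voting Recognition of Grammatical Facial
    Expressions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Recognition of grammatical facial expressions (GFEs) from 3D
    facial-landmark streams such as those produced by a Kinect sensor.
    Per-frame geometric features (Euclidean distances, inter-segment
    angles, depths, and polygon area/eccentricity shape descriptors) are
    assembled into sliding-window samples, each window's feature vector is
    split into three contiguous "perspectives", one probabilistic
    random-forest classifier is trained per perspective, and their class
    probabilities are fused by weighted soft voting. Includes stratified
    k-fold and cross-subject evaluation protocols with class balancing,
    F1/accuracy/ROC-AUC reporting, a synthetic labeled landmark-stream
    generator for end-to-end testing, and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    caret,
    jsonlite,
    optparse,
    pROC,
    ranger,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr
Config/testthat/edition: 3
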