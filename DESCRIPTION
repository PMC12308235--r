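Package: stagpose
Title: Behavioural Scoring of Dyadic Stag-Beetle Trials from Pose-Estimation Tracks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns multi-animal markerless pose-estimation output (two
    individuals, five labelled body parts each) into quantitative
    behavioural endpoints for 10-minute dyadic arena trials. Provides
    readers and writers for the four-header-row multi-animal coordinate
    CSV dialect, likelihood-cutoff conditioning with gap interpolation
    and pixel-to-centimetre calibration, per-individual locomotor
    endpoints (distance, speed, freezing/normal/rapid partition,
    thigmotaxis), dyadic endpoints from thresholded inter-body-part
    distance series (mandible extension, mandible contact, chasing,
    interaction) with bout detection, pairwise aggression indices,
    multivariate summaries (z-scored PCA, average-linkage clustering
    with silhouettes, Pearson correlation against morphology), and a
    semi-Markov trajectory simulator with a ground-truth log so the
    whole pipeline is testable without video.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    cluster,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
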