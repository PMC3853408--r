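Package: migamma
Title: Resting-State Gamma Band Power and Motor-Imagery BCI Performance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools linking resting-state spectral band power to motor-imagery
    brain-computer-interface (BCI) performance in multichannel M/EEG recordings.
    Implements the common-spatial-pattern (CSP) plus Fisher linear discriminant
    performance estimator with grouped exhaustive-partition cross-validation in a
    sliding window, the relative power level (RPL) band statistic for resting
    recordings, region-wise and channel-wise Pearson correlation maps with
    Benjamini-Hochberg false-discovery-rate correction, and a synthetic M/EEG
    cohort generator with known event-related-desynchronization ground truth and
    a configurable coupling between prefrontal resting gamma amplitude and
    imagery-induced desynchronization depth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
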