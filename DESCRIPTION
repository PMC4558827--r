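Package: elewatch
Title: Acoustic and Visual Detection of Elephants for Early-Warning
    Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A toolkit for detecting free-ranging elephants in field
    recordings. The acoustic pipeline detects low-frequency rumbles in
    mono audio: spectrogram enhancement that boosts well-localized
    spectro-temporal ridges, Greenwood-warped cepstral features (GFCC)
    aggregated over context windows, a linear support-vector classifier,
    and interval-level event decisions scored against label-track
    annotations. The visual pipeline detects elephants in color frame
    sequences: a linear skin-color model in CIELAB space, mean-shift
    over-segmentation, and temporal linking, merging and refinement of
    candidate segments into tracks scored against per-pixel masks.
    Seeded synthetic soundscape and scene generators provide annotated
    benchmarks for both pipelines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    grDevices,
    jsonlite,
    png,
    Rcpp,
    signal,
    stats,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
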