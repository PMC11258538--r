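Package: lickwise
Title: Lickometer Validation, Lick Microstructure, and Fiber Photometry
    Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for optical lickometer recordings in freely
    moving mice: scoring of sensor beam-break events against video-defined
    tongue protrusions (precision, recall, miss enrichment by lick type via
    Fisher's exact test), a post hoc artifact filter based on lick duration
    and interlick-interval criteria, lick-microstructure statistics (bouts,
    modal and primary interlick intervals), a behavioural-task simulator
    with truncated-exponential intertrial intervals and bout-triggered
    rewards, and a fiber-photometry processing chain (robust locally
    weighted regression detrending, isosbestic subtraction, z-scoring,
    peri-event time histograms, and two-way repeated-measures comparison of
    rewarded versus unrewarded licks). A synthetic-data module generates
    ground-truth sessions, corrupted sensor streams, pose tracks, and
    photometry traces so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
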