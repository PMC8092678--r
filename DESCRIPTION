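Package: prososeg
Title: Training-Free Prosodic Phrase Boundary Detection from Forced-Alignment Timings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects prosodic phrase (intonation unit) boundaries in
    spontaneous speech from forced-alignment word and phone timings alone,
    without model training. Boundaries are placed at word onsets flagged by
    discontinuities in local speech rate (pre-boundary lengthening followed
    by phrase-initial acceleration) or by silent pauses. Includes the full
    validation stack: boundary-agreement scoring against reference
    segmentations (precision, recall, F-score, accuracy, Cohen's kappa,
    chi-square contrasts), phrase-level pitch declination and reset
    statistics on time-normalized contours, positional duration and lexical
    statistics, and a seeded synthetic-conversation generator with ground
    truth so the whole pipeline is testable without corpus access. Reads
    Praat TextGrid files and a plain tab-separated alignment format.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
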