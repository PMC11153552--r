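Package: circalux
Title: Circadian Analysis of Bioluminescence Plate Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of circadian bioluminescence recordings from multi-well
    plate luminometers, as used for luciferase reporter assays in C. elegans
    and other organisms. Provides reading and writing of long- or wide-format
    plate CSVs with zeitgeber protocol schedules, preprocessing of raw counts
    (background subtraction, initial-transient truncation, moving-average
    detrending and smoothing, normalization), Lomb-Scargle period estimation
    restricted to the circadian band, cosinor rhythmometry with
    Synchronized/Circadian/Arrhythmic classification, circular statistics of
    peak phases (mean vector, resultant length, Rayleigh test), a seeded
    synthetic-plate generator with known ground truth, and an end-to-end
    analysis pipeline with group summaries and plots.
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
    grDevices,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
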