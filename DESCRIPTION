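Package: bimon
Title: Bioimpedance Monitoring of Secondary Brain Injury
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for multichannel intracranial
    bioimpedance monitoring of secondary brain injury. Generates ground-truthed
    eight-channel tetrapolar impedance recordings with intracranial pressure
    (ICP) under a staged injury protocol (balloon mass effect, hematoma,
    osmotic therapy, terminal event), demodulates carrier-level signals with a
    matched filter, removes CT-burst, DC-shift and droplet artifacts, and
    computes the event metrics used to detect and identify injury: impedance
    change from baseline, the discriminatory index (impedance change over
    pressure change), threshold-based volume-change detection, normalized
    channel maps for focal-injury localization, and channel-variance statistics
    (Levene, Welch, analysis of means) separating focal from global events.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
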