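Package: reefpatch
Title: Reef Condition Scoring and Patchiness Statistics for Drop-Down
    Video Transects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing the condition of Sabellaria spinulosa
    biogenic reef from drop-down video transects. Raw analyst annotations
    are binned into fixed-duration (default 5-second) segments, each
    segment is scored for percentage cover and tube elevation and mapped
    to an ordinal reef-status class through a cover-by-elevation reef
    structure matrix, and along-transect clustering of reef presence is
    quantified with a randomization-based "true patchiness" statistic K
    (observed mean patch size over the mean patch size under random
    arrangement) with a permutation p-value. Includes an exhaustive
    enumeration oracle for small sequences, per-tow summary tables,
    a Markov-chain synthetic transect generator, and a command-line
    front-end for reproducible monitoring pipelines.
License: MIT + file LICENSE
Encoding: UTF-8
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
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
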