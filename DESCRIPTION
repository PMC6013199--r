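Package: evacmargin
Title: Tsunami Evacuation Time-Budget Modelling for Power-Dependent
    Homecare Recipients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models whether medically dependent homecare recipients can be
    evacuated to welfare evacuation shelters before a tsunami arrives. A
    visiting nurse drives from the network-nearest nursing station, transfers
    the recipient to a wheelchair, and pushes the wheelchair to the nearest
    shelter outside the worst inundation zone; the margin between the 30-cm
    tsunami arrival time at the shelter and the total evacuation time
    classifies delayed escapes. Provides road-network routing over polyline
    data, point-in-polygon hazard zoning, nearest-facility assignment under a
    flood-level constraint, one-way and 16-scenario multi-way sensitivity
    analysis, a seeded synthetic coastal-city scenario generator, and a
    packaged transcription of the Kochi City study-area inputs.
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
    igraph,
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
    sp,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
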