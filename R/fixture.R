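#' Packaged study-area inputs: homecare recipients of Kochi City
#'
#' The published Kochi City analysis identified 21 power-dependent homecare
#' recipients living inside the predicted tsunami inundation area. For each,
#' the original GIS workflow measured the road-network distance from the
#' nearest visiting nursing station to the home, the distance from the home to
#' the assigned welfare evacuation shelter, and the predicted time for a 30-cm
#' tsunami flow to reach that shelter. This function returns a verbatim
#' transcription of those per-recipient inputs so the whole downstream
#' pipeline (timing, classification, sensitivity analysis) can be exercised
#' and reproduced without any geodata.
#'
#' Four recipients (IDs 3, 8, 14 and 29) live outside the area reached by a
#' 30-cm tsunami; their `arrival_min` is `NA` and their evacuation margin is
#' undefined throughout the pipeline. `seismic_intensity` (JMA intensity
#' class) and `inundation_band` (maximum inundation depth band, metres) are
#' descriptive attributes carried along verbatim, never computed on.
#'
#' @return A tibble with 21 rows and columns `id` (character), `seismic_intensity`,
#'   `inundation_band`, `d_station` (metres, station to home), `d_shelter`
#'   (metres, home to shelter) and `arrival_min` (minutes, `NA` when the
#'   shelter lies outside the 30-cm arrival field). Row order follows the
#'   published table.
#' @examples
#' kochi_recipients()
#' @export
kochi_recipients <- function() {
  tibble::tribble(
    ~id,  ~seismic_intensity, ~inundation_band, ~d_station, ~d_shelter, ~arrival_min,
    "3",  "6+", "0.0-0.3", 599,  1892, NA,
    "8",  "6+", "0.3-1.0", 811,  2125, NA,
    "14", "7",  "0.3-1.0", 951,  2096, NA,
    "22", "6+", "0.3-1.0", 2694, 4543, 60,
    "27", "7",  "0.3-1.0", 1324, 1418, 60,
    "48", "6+", "0.3-1.0", 1748, 1336, 60,
    "11", "7",  "1.0-2.0", 1821, 2110, 60,
    "18", "6+", "1.0-2.0", 795,  265,  50,
    "19", "7",  "2.0-3.0", 2034, 2035, 50,
    "21", "7",  "1.0-2.0", 1844, 3324, 35,
    "29", "6+", "2.0-3.0", 840,  1682, NA,
    "30", "7",  "1.0-2.0", 1245, 2724, 35,
    "32", "7",  "2.0-3.0", 637,  655,  50,
    "39", "6+", "1.0-2.0", 975,  866,  60,
    "46", "6+", "2.0-3.0", 781,  1830, 60,
    "47", "6-", "2.0-3.0", 1118, 483,  60,
    "51", "6+", "1.0-2.0", 1146, 3909, 35,
    "5",  "6+", "3.0-5.0", 745,  912,  50,
    "34", "6-", "3.0-5.0", 56,   522,  50,
    "49", "6+", "3.0-5.0", 584,  1074, 50,
    "50", "6+", "3.0-5.0", 2081, 332,  35
  )
}
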