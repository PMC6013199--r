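#' Configuration for a synthetic coastal-city scenario
#'
#' Describes a stylised coastal city with the statistical structure of the
#' Kochi study area: the coastline is the line `y = 0`, the tsunami
#' propagates inland in the +y direction, inundation severity and arrival
#' time are banded parallel to the coast, and roads form a regular grid with
#' random edge dropout. Defaults mirror the study area: 21 recipients inside
#' the inundation area, 9 nursing stations, 33 shelters; station-to-home
#' network distances within 50-2,700 m and home-to-eligible-shelter
#' distances within 300-4,600 m (enforced by rejection sampling); arrival
#' bands of 35/50/60 min at increasing distance from the coast, undefined
#' beyond the last band.
#'
#' @param seed Integer seed; the generator is a pure function of the config.
#' @param extent `c(width, depth)` of the city in metres.
#' @param road_spacing Grid spacing in metres.
#' @param edge_dropout Fraction of grid edges removed at random (< 1); the
#'   dropout is re-drawn until the road graph stays connected.
#' @param n_recipients,n_stations,n_shelters Site counts (>= 1; shelters may
#'   be 0 only never - validated).
#' @param level_depths Named or unnamed increasing vector of three inland
#'   depths (metres from the coast) bounding inundation levels 3, 2, 1.
#' @param arrival_bands Named numeric vector: names are inland depths
#'   (metres) bounding each band, values are arrival minutes, increasing with
#'   distance from the coast.
#' @param station_range,shelter_range Acceptance envelopes (metres, network
#'   distance) for recipient placement.
#' @param shelter_y_range Optional `c(min, max)` restricting shelter
#'   placement in y, e.g. to force every shelter into the level-3 band for
#'   degenerate-case testing.
#' @param max_tries Rejection-sampling attempts per recipient.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(seed = 1L,
                            extent = c(5000, 5000),
                            road_spacing = 250,
                            edge_dropout = 0.1,
                            n_recipients = 21L,
                            n_stations = 9L,
                            n_shelters = 33L,
                            level_depths = c(800, 1800, 2800),
                            arrival_bands = c(`1200` = 35, `2400` = 50, `3600` = 60),
                            station_range = c(50, 2700),
                            shelter_range = c(300, 4600),
                            shelter_y_range = NULL,
                            max_tries = 500L) {
  stopifnot(is_number(seed), length(extent) == 2L, all(extent > 0),
            is_number(road_spacing), road_spacing > 0,
            is_number(edge_dropout), edge_dropout >= 0, edge_dropout < 1,
            is_number(max_tries), max_tries >= 1)
  counts <- c(n_recipients = n_recipients, n_stations = n_stations,
              n_shelters = n_shelters)
  if (any(counts < 1)) {
    abort(sprintf("infeasible scenario: %s must be >= 1",
                  paste(names(counts)[counts < 1], collapse = ", ")))
  }
  if (length(level_depths) != 3L || is.unsorted(level_depths, strictly = TRUE)) {
    abort("level_depths must be three strictly increasing inland depths")
  }
  depths <- as.numeric(names(arrival_bands))
  if (anyNA(depths) || is.unsorted(depths, strictly = TRUE) ||
      is.unsorted(arrival_bands, strictly = TRUE) || any(arrival_bands <= 0)) {
    abort("arrival_bands must map strictly increasing depths to strictly increasing positive minutes")
  }
  if (!is.null(shelter_y_range)) stopifnot(length(shelter_y_range) == 2L)
  structure(list(seed = as.integer(seed), extent = extent,
                 road_spacing = road_spacing, edge_dropout = edge_dropout,
                 n_recipients = as.integer(n_recipients),
                 n_stations = as.integer(n_stations),
                 n_shelters = as.integer(n_shelters),
                 level_depths = unname(level_depths),
                 arrival_bands = arrival_bands,
                 station_range = station_range, shelter_range = shelter_range,
                 shelter_y_range = shelter_y_range,
                 max_tries = as.integer(max_tries)),
            class = "scenario_config")
}

# one polyline per grid edge, so snapped endpoints become the grid nodes
grid_polylines <- function(extent, spacing) {
  xs <- seq(0, extent[1], by = spacing)
  ys <- seq(0, extent[2], by = spacing)
  polys <- list()
  for (yi in ys) for (i in seq_len(length(xs) - 1L)) {
    polys[[length(polys) + 1L]] <-
      matrix(c(xs[i], yi, xs[i + 1L], yi), ncol = 2, byrow = TRUE)
  }
  for (xi in xs) for (j in seq_len(length(ys) - 1L)) {
    polys[[length(polys) + 1L]] <-
      matrix(c(xi, ys[j], xi, ys[j + 1L]), ncol = 2, byrow = TRUE)
  }
  polys
}

band_zone <- function(x0, x1, y0, y1, value) {
  list(rings = list(matrix(c(x0, y0, x1, y0, x1, y1, x0, y1), ncol = 2,
                           byrow = TRUE)),
       value = value)
}

#' Generate a seeded synthetic coastal-city scenario
#'
#' Deterministic given the config (same config, byte-identical output). The
#' road grid keeps being re-dropped until it is connected; recipients are
#' placed inside the inundation area by rejection sampling until their
#' network distances to the nearest station and nearest *eligible* shelter
#' fall inside the configured envelopes (the shelter criterion is waived when
#' the config leaves no eligible shelter at all, so degenerate scenarios can
#' be generated on purpose).
#'
#' @param config A [scenario_config()].
#' @return List with `sites` (tibble `id`, `role`, `x`, `y`), `roads` (list
#'   of polyline matrices), `hazard` (a `hazard_fields`), `graph` (the built
#'   `road_graph`) and `config`.
#' @export
generate_scenario <- function(config = scenario_config()) {
  stopifnot(inherits(config, "scenario_config"))
  withr::with_seed(config$seed, generate_scenario_impl(config))
}

generate_scenario_impl <- function(config) {
  extent <- config$extent
  polys <- grid_polylines(extent, config$road_spacing)

  # drop edges, retrying until the graph stays connected
  graph <- NULL
  for (try in 1:50) {
    keep <- stats::runif(length(polys)) >= config$edge_dropout
    if (!any(keep)) next
    g <- suppressWarnings(build_road_graph(polys[keep],
                                           snap_tolerance = config$road_spacing / 100))
    if (igraph::is_connected(g$graph)) { graph <- g; break }
  }
  if (is.null(graph)) abort("could not generate a connected road network; lower edge_dropout")

  # hazard bands parallel to the coast (y = 0), extended past the city edge
  pad <- config$road_spacing
  ld <- config$level_depths
  level_zones <- list(
    band_zone(-pad, extent[1] + pad, 0, ld[1], 3),
    band_zone(-pad, extent[1] + pad, ld[1], ld[2], 2),
    band_zone(-pad, extent[1] + pad, ld[2], ld[3], 1))
  depths <- as.numeric(names(config$arrival_bands))
  lower <- c(0, depths[-length(depths)])
  arrival_zones <- purrr::map(seq_along(depths), function(i) {
    band_zone(-pad, extent[1] + pad, lower[i], depths[i],
              unname(config$arrival_bands[i]))
  })
  hazard <- hazard_fields(level_zones, arrival_zones)

  runif_xy <- function(n, y_range) {
    tibble(x = stats::runif(n, 0, extent[1]),
           y = stats::runif(n, y_range[1], y_range[2]))
  }

  shelter_y <- config$shelter_y_range %||% c(0, extent[2])
  shelters <- runif_xy(config$n_shelters, shelter_y) |>
    dplyr::mutate(id = sprintf("SH%02d", dplyr::row_number()), role = "shelter")
  stations <- runif_xy(config$n_stations, c(0, extent[2])) |>
    dplyr::mutate(id = sprintf("ST%02d", dplyr::row_number()), role = "station")

  # distance lookups reused by every placement attempt
  station_nodes <- snap_site(graph, stations$x, stations$y)$node
  shelter_level <- flood_level_at(hazard, shelters$x, shelters$y)
  eligible <- is.na(shelter_level) | shelter_level <= 2L
  d_station_all <- t(network_distances(graph, station_nodes, graph$nodes$node))
  if (any(eligible)) {
    elig_nodes <- snap_site(graph, shelters$x[eligible], shelters$y[eligible])$node
    d_shelter_all <- t(network_distances(graph, elig_nodes, graph$nodes$node))
  }

  # recipients live inside the inundation area; rejection-sample placements
  # until network distances fall in the configured envelopes
  rec_x <- rec_y <- numeric(config$n_recipients)
  for (i in seq_len(config$n_recipients)) {
    placed <- FALSE
    for (try in seq_len(config$max_tries)) {
      cand <- runif_xy(1L, c(0, config$level_depths[3]))
      node <- snap_site(graph, cand$x, cand$y)$node
      ni <- match(node, graph$nodes$node)
      d_st <- min(d_station_all[ni, ])
      ok_st <- is.finite(d_st) &&
        d_st >= config$station_range[1] && d_st <= config$station_range[2]
      ok_sh <- TRUE
      if (any(eligible)) {
        d_sh <- min(d_shelter_all[ni, ])
        ok_sh <- is.finite(d_sh) &&
          d_sh >= config$shelter_range[1] && d_sh <= config$shelter_range[2]
      }
      if (ok_st && ok_sh) {
        rec_x[i] <- cand$x; rec_y[i] <- cand$y
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      abort(sprintf("could not place recipient %d within the configured distance envelopes", i))
    }
  }
  recipients <- tibble(x = rec_x, y = rec_y,
                       id = sprintf("R%02d", seq_len(config$n_recipients)),
                       role = "recipient")

  sites <- dplyr::bind_rows(recipients, stations, shelters) |>
    dplyr::select("id", "role", "x", "y")
  list(sites = sites, roads = polys[keep], hazard = hazard,
       graph = graph, config = config)
}

#' Write a generated scenario to disk in the interchange formats
#'
#' Emits exactly the formats the readers consume - `sites.csv`,
#' `roads.geojson`, `levels.geojson`, `arrival.geojson` - so synthetic and
#' real inputs are interchangeable.
#'
#' @param scenario Output of [generate_scenario()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_sites(scenario$sites, file.path(dir, "sites.csv"))
  write_roads_geojson(scenario$roads, file.path(dir, "roads.geojson"))
  write_zones_geojson(scenario$hazard$level_zones,
                      file.path(dir, "levels.geojson"), "level")
  write_zones_geojson(scenario$hazard$arrival_zones,
                      file.path(dir, "arrival.geojson"), "arrival_min")
  invisible(dir)
}
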