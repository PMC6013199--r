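#' Read a site table (recipients, nursing stations, or shelters)
#'
#' Sites are plain CSV with at least `id`, `x` and `y` columns; coordinates
#' are planar metres in a projected CRS (all model arithmetic is metres and
#' minutes). Any further columns are kept verbatim as descriptive attributes.
#' Thousands separators in numeric columns are stripped on read.
#'
#' @param path Path to a CSV file with a header row.
#' @param role Site role to stamp on every row: `"recipient"`, `"station"` or
#'   `"shelter"`. If `NULL` the file must carry its own `role` column.
#' @return A tibble with columns `id` (character), `role`, `x`, `y` and any
#'   attribute columns, one row per input row in file order.
#' @export
read_sites <- function(path, role = NULL) {
  if (!file.exists(path)) abort(sprintf("site file does not exist: %s", path))
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         strip.white = TRUE)
  raw <- tibble::as_tibble(raw)
  if (nrow(raw) == 0L && !all(c("id", "x", "y") %in% names(raw))) {
    abort(sprintf("site file %s has no usable header (need id, x, y)", path))
  }
  assert_columns(raw, c("id", "x", "y"), sprintf("site file %s", path))
  if (is.null(role)) {
    assert_columns(raw, "role", sprintf("site file %s", path))
  } else {
    role <- match.arg(role, c("recipient", "station", "shelter"))
    raw$role <- rep(role, nrow(raw))
  }
  if (anyDuplicated(raw$id)) {
    dup <- unique(raw$id[duplicated(raw$id)])
    abort(sprintf("duplicate site id(s) in %s: %s", path,
                  paste(dup, collapse = ", ")))
  }
  for (col in c("x", "y")) {
    val <- suppressWarnings(as.numeric(gsub(",", "", raw[[col]])))
    bad <- which(!is.na(raw[[col]]) & raw[[col]] != "" & is.na(val))
    if (length(bad) > 0L) {
      abort(sprintf("non-numeric %s coordinate in %s at row(s) %s",
                    col, path, paste(bad, collapse = ", ")))
    }
    if (anyNA(val) || any(!is.finite(val))) {
      abort(sprintf("missing or non-finite %s coordinate in %s", col, path))
    }
    raw[[col]] <- val
  }
  dplyr::relocate(raw, "id", "role", "x", "y")
}

#' Write a site table
#'
#' @param sites Tibble as returned by [read_sites()] or found in a generated
#'   scenario's `sites` element.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sites <- function(sites, path) {
  assert_columns(sites, c("id", "role", "x", "y"), "site table")
  utils::write.csv(sites, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

# Column order of the published per-recipient result table.
timing_columns <- c(
  "id", "seismic_intensity", "inundation_band",
  "d_station", "t_nurse", "t_transfer",
  "d_shelter", "t_walk", "t_total",
  "arrival_min", "margin", "delayed"
)

#' Write per-recipient evacuation timing results
#'
#' Writes the result table in the published column order: recipient id, the
#' two descriptive hazard attributes, then distance/time pairs for the nurse
#' leg and the wheelchair leg, total time, tsunami arrival deadline, margin
#' and the delayed-escape flag. Times are displayed to 0.1 min (half away
#' from zero); undefined values (recipients outside the 30-cm arrival field)
#' are written as the literal token `n/a`.
#'
#' @param timing An `evac_timing` tibble from [compute_timing()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_timing <- function(timing, path) {
  assert_columns(timing, setdiff(timing_columns, c("seismic_intensity", "inundation_band")),
                 "timing table")
  out <- as.data.frame(timing)
  for (col in setdiff(timing_columns, names(out))) out[[col]] <- NA_character_
  out <- out[timing_columns]
  for (col in c("t_nurse", "t_transfer", "t_walk", "t_total", "margin")) {
    out[[col]] <- round_display(out[[col]], 1)
  }
  out$delayed <- ifelse(is.na(out$delayed), NA, ifelse(out$delayed, "yes", "no"))
  for (col in names(out)) {
    v <- as.character(out[[col]])
    v[is.na(v)] <- "n/a"
    out[[col]] <- v
  }
  con <- tryCatch(file(path, "w"), error = function(e) {
    abort(sprintf("cannot open %s for writing: %s", path, conditionMessage(e)))
  })
  on.exit(close(con))
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read back a timing results table
#'
#' Inverse of [write_timing()] at display precision: `n/a` tokens become `NA`
#' and numeric columns are parsed back to doubles.
#'
#' @param path CSV path written by [write_timing()].
#' @return Tibble in the same column order.
#' @export
read_timing <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  raw <- tibble::as_tibble(raw)
  raw[raw == "n/a"] <- NA
  num_cols <- c("d_station", "t_nurse", "t_transfer", "d_shelter",
                "t_walk", "t_total", "arrival_min", "margin")
  for (col in intersect(num_cols, names(raw))) {
    raw[[col]] <- as.numeric(gsub(",", "", raw[[col]]))
  }
  if ("delayed" %in% names(raw)) raw$delayed <- raw$delayed == "yes"
  raw
}

# ---- GeoJSON ---------------------------------------------------------------
# Minimal GeoJSON support for the four geometry types the pipeline uses
# (LineString, MultiLineString, Polygon, MultiPolygon) with flat properties.
# Coordinates are planar metres; no CRS transformation is attempted.

geojson_read <- function(path) {
  if (!file.exists(path)) abort(sprintf("GeoJSON file does not exist: %s", path))
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(gj$type, "FeatureCollection")) {
    abort(sprintf("%s: expected a GeoJSON FeatureCollection", path))
  }
  gj$features
}

coords_matrix <- function(ring) {
  m <- matrix(unlist(ring, use.names = FALSE), ncol = 2, byrow = TRUE)
  storage.mode(m) <- "double"
  m
}

#' Read road polylines from GeoJSON
#'
#' Accepts LineString and MultiLineString features; each (sub)linestring
#' becomes one polyline, i.e. one candidate edge for [build_road_graph()].
#'
#' @param path GeoJSON FeatureCollection path.
#' @return A list of two-column coordinate matrices (x, y in metres).
#' @export
read_roads_geojson <- function(path) {
  feats <- geojson_read(path)
  polys <- list()
  for (f in feats) {
    geom <- f$geometry
    if (is.null(geom)) next
    if (identical(geom$type, "LineString")) {
      polys[[length(polys) + 1L]] <- coords_matrix(geom$coordinates)
    } else if (identical(geom$type, "MultiLineString")) {
      for (part in geom$coordinates) {
        polys[[length(polys) + 1L]] <- coords_matrix(part)
      }
    } else {
      warn(sprintf("skipping non-line geometry of type %s", geom$type))
    }
  }
  polys
}

ring_to_list <- function(m) {
  lapply(seq_len(nrow(m)), function(i) c(m[i, 1], m[i, 2]))
}

#' Write road polylines to GeoJSON
#'
#' @param polylines List of two-column coordinate matrices.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_roads_geojson <- function(polylines, path) {
  feats <- lapply(polylines, function(m) {
    list(type = "Feature", properties = list(length_m = polyline_length(m)),
         geometry = list(type = "LineString", coordinates = ring_to_list(m)))
  })
  gj <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read hazard zones from GeoJSON
#'
#' Polygon/MultiPolygon features carrying a numeric property (`level` for
#' inundation-level zones, `arrival_min` for 30-cm tsunami arrival-time
#' zones). All rings of a polygon participate in even-odd containment, so
#' holes are honoured.
#'
#' @param path GeoJSON FeatureCollection path.
#' @param property Name of the numeric property to attach to each zone.
#' @return A list of zones, each `list(rings = <list of matrices>, value = <number>)`.
#' @export
read_zones_geojson <- function(path, property) {
  feats <- geojson_read(path)
  zones <- list()
  for (f in feats) {
    geom <- f$geometry
    if (is.null(geom)) next
    value <- f$properties[[property]]
    if (is.null(value)) {
      abort(sprintf("%s: feature missing required property '%s'", path, property))
    }
    value <- as.numeric(value)
    if (identical(geom$type, "Polygon")) {
      rings <- lapply(geom$coordinates, coords_matrix)
      zones[[length(zones) + 1L]] <- list(rings = rings, value = value)
    } else if (identical(geom$type, "MultiPolygon")) {
      for (poly in geom$coordinates) {
        rings <- lapply(poly, coords_matrix)
        zones[[length(zones) + 1L]] <- list(rings = rings, value = value)
      }
    } else {
      warn(sprintf("skipping non-polygon geometry of type %s", geom$type))
    }
  }
  zones
}

#' Write hazard zones to GeoJSON
#'
#' @param zones List of zones as returned by [read_zones_geojson()].
#' @param path Output path.
#' @param property Property name under which each zone's value is stored.
#' @return `path`, invisibly.
#' @export
write_zones_geojson <- function(zones, path, property) {
  feats <- lapply(zones, function(z) {
    props <- list()
    props[[property]] <- z$value
    list(type = "Feature", properties = props,
         geometry = list(type = "Polygon",
                         coordinates = lapply(z$rings, ring_to_list)))
  })
  gj <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write computed routes to GeoJSON
#'
#' Each route becomes a LineString feature through its node coordinates with
#' `length_m` and endpoint ids as properties; unreachable routes are skipped.
#'
#' @param routes List of routes from [shortest_route()].
#' @param graph The `road_graph` the routes were computed on.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_routes_geojson <- function(routes, graph, path) {
  stopifnot(inherits(graph, "road_graph"))
  feats <- list()
  for (r in routes) {
    if (!isTRUE(r$reachable)) next
    idx <- match(r$nodes, graph$nodes$node)
    coords <- cbind(graph$nodes$x[idx], graph$nodes$y[idx])
    if (nrow(coords) == 1L) coords <- coords[c(1L, 1L), , drop = FALSE]
    feats[[length(feats) + 1L]] <- list(
      type = "Feature",
      properties = list(length_m = r$length_m,
                        from = r$nodes[1L], to = r$nodes[length(r$nodes)]),
      geometry = list(type = "LineString", coordinates = ring_to_list(coords)))
  }
  gj <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
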