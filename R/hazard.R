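#' Hazard fields: inundation-level polygons and 30-cm arrival-time zones
#'
#' Bundles the two polygon layers the evacuation model queries: predicted
#' inundation-level zones (ordinal severity 1-3; level-3 areas are barred as
#' shelter destinations) and the zones giving the predicted time, in minutes,
#' for a 30-cm tsunami flow to arrive.
#'
#' Each zone is `list(rings = <list of two-column matrices>, value = <number>)`;
#' rings beyond the first are holes (even-odd rule). Overlaps are resolved
#' conservatively: the *maximum* level and the *minimum* arrival time.
#'
#' @param level_zones List of zones with integer `value` in 1..3.
#' @param arrival_zones List of zones with positive `value` in minutes.
#' @return A `hazard_fields` object.
#' @export
hazard_fields <- function(level_zones = list(), arrival_zones = list()) {
  check_zone <- function(z, what, values_ok) {
    if (!is.list(z) || is.null(z$rings) || is.null(z$value)) {
      abort(sprintf("%s zone must be list(rings=, value=)", what))
    }
    for (r in z$rings) {
      if (!is.matrix(r) || ncol(r) != 2L || nrow(r) < 3L) {
        abort(sprintf("%s zone ring must be a matrix of >= 3 points", what))
      }
    }
    if (!values_ok(z$value)) abort(sprintf("invalid %s zone value: %s", what, z$value))
    z$value <- as.numeric(z$value)
    z
  }
  level_zones <- lapply(level_zones, check_zone, what = "level",
                        values_ok = function(v) is_number(v) && v %in% 1:3)
  arrival_zones <- lapply(arrival_zones, check_zone, what = "arrival",
                          values_ok = function(v) is_number(v) && v > 0)
  structure(list(level_zones = level_zones, arrival_zones = arrival_zones),
            class = "hazard_fields")
}

#' @export
print.hazard_fields <- function(x, ...) {
  cat(sprintf("<hazard_fields> %d inundation-level zone(s), %d arrival-time zone(s)\n",
              length(x$level_zones), length(x$arrival_zones)))
  invisible(x)
}

#' Read both hazard layers from GeoJSON
#'
#' @param level_path GeoJSON of inundation polygons with a `level` property.
#' @param arrival_path GeoJSON of arrival-time polygons with an `arrival_min`
#'   property.
#' @return A `hazard_fields` object.
#' @export
read_hazard_geojson <- function(level_path, arrival_path) {
  hazard_fields(level_zones = read_zones_geojson(level_path, "level"),
                arrival_zones = read_zones_geojson(arrival_path, "arrival_min"))
}

# Boundary-inclusive even-odd containment for one polygon (outer ring plus
# optional holes). Ray casting with a horizontal ray to +infinity; a point
# lying on any ring edge counts as inside, so sites exactly on a zone
# boundary never silently escape hazard classification.
point_in_rings <- function(px, py, rings, eps = 1e-9) {
  crossings <- 0L
  for (ring in rings) {
    n <- nrow(ring)
    xs <- ring[, 1L]; ys <- ring[, 2L]
    j <- c(n, seq_len(n - 1L))  # previous vertex (closes the ring)
    for (i in seq_len(n)) {
      x1 <- xs[j[i]]; y1 <- ys[j[i]]; x2 <- xs[i]; y2 <- ys[i]
      # on-segment test
      scale <- max(abs(c(x1, y1, x2, y2, px, py, 1)))
      cross <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
      if (abs(cross) <= eps * scale &&
          px >= min(x1, x2) - eps * scale && px <= max(x1, x2) + eps * scale &&
          py >= min(y1, y2) - eps * scale && py <= max(y1, y2) + eps * scale) {
        return(TRUE)
      }
      # crossing test (half-open in y so shared vertices count once)
      if ((y1 > py) != (y2 > py)) {
        xint <- x1 + (py - y1) * (x2 - x1) / (y2 - y1)
        if (px < xint) crossings <- crossings + 1L
      }
    }
  }
  (crossings %% 2L) == 1L
}

query_zones <- function(zones, x, y, combine) {
  purrr::map2_dbl(x, y, function(px, py) {
    vals <- purrr::map_dbl(zones, function(z) {
      if (point_in_rings(px, py, z$rings)) z$value else NA_real_
    })
    vals <- vals[!is.na(vals)]
    if (length(vals) == 0L) NA_real_ else combine(vals)
  })
}

#' Inundation level at point(s)
#'
#' @param fields A `hazard_fields` object.
#' @param x,y Planar coordinates (metres), vectorised.
#' @return Integer vector of levels 1-3; `NA` outside every level polygon.
#'   Overlapping polygons yield the maximum (worst-case) level.
#' @export
flood_level_at <- function(fields, x, y) {
  stopifnot(inherits(fields, "hazard_fields"))
  as.integer(query_zones(fields$level_zones, x, y, max))
}

#' 30-cm tsunami arrival time at point(s)
#'
#' @param fields A `hazard_fields` object.
#' @param x,y Planar coordinates (metres), vectorised.
#' @return Numeric vector of minutes; `NA` outside every arrival zone (the
#'   location is not reached by a 30-cm tsunami). Overlapping zones yield the
#'   minimum (worst-case, earliest) arrival time.
#' @export
arrival_time_at <- function(fields, x, y) {
  stopifnot(inherits(fields, "hazard_fields"))
  query_zones(fields$arrival_zones, x, y, min)
}
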