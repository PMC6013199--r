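#' Model parameters of the evacuation time budget
#'
#' Base values follow the published Kochi City analysis: the visiting nurse
#' drives at 360 m/min (the measured average urban car speed there), the
#' bed-to-wheelchair transfer takes 4.9 min (national visiting-nurse survey
#' average), and the wheelchair is pushed at 33.3 m/min. The wheelchair speed
#' is taken from the published result-table header; the study text quotes the
#' source speed as 1.88 km/h (31.3 m/min), but only 33.3 m/min reproduces the
#' published walk times (e.g. 4,543 m -> 136.4 min), so the header value is
#' treated as the value actually used.
#'
#' @param nurse_speed Nurse travel speed, m/min (> 0).
#' @param walk_speed Wheelchair travel speed, m/min (> 0).
#' @param transfer_time Bed-to-wheelchair transfer time, min (> 0).
#' @return A `model_parameters` list.
#' @examples
#' model_parameters()
#' model_parameters(walk_speed = 16.65)
#' @export
model_parameters <- function(nurse_speed = 360, walk_speed = 33.3,
                             transfer_time = 4.9) {
  for (v in c(nurse_speed = nurse_speed, walk_speed = walk_speed,
              transfer_time = transfer_time)) {
    if (!is_number(v) || v <= 0) abort("model parameters must be positive numbers")
  }
  structure(list(nurse_speed = nurse_speed, walk_speed = walk_speed,
                 transfer_time = transfer_time),
            class = "model_parameters")
}

#' @export
print.model_parameters <- function(x, ...) {
  cat(sprintf(
    "<model_parameters> nurse %.4g m/min, wheelchair %.4g m/min, transfer %.4g min\n",
    x$nurse_speed, x$walk_speed, x$transfer_time))
  invisible(x)
}

# nearest site by network distance with deterministic tie-break by site id
nearest_by_network <- function(dists, site_ids) {
  # dists: numeric vector over sites (Inf = unreachable)
  ok <- is.finite(dists)
  if (!any(ok)) return(NULL)
  ord <- order(dists, site_ids)
  list(id = site_ids[ord[1L]], d = unname(dists[ord[1L]]))
}

#' Assign the nearest visiting nursing station to each recipient
#'
#' The nurse rescuer departs from the station nearest the recipient's home by
#' road-network distance (ties broken by station id). Sites are routed from
#' their nearest graph node; the off-network offset is diagnostic only and
#' not added to the distance.
#'
#' @param recipients,stations Site tibbles with `id`, `x`, `y` columns.
#' @param graph A `road_graph`.
#' @return Tibble: `recipient_id`, `station_id`, `d_station` (metres).
#' @export
assign_station <- function(recipients, stations, graph) {
  assert_columns(recipients, c("id", "x", "y"), "recipients")
  assert_columns(stations, c("id", "x", "y"), "stations")
  if (nrow(stations) == 0L) abort("at least one nursing station is required")
  rn <- snap_site(graph, recipients$x, recipients$y)$node
  sn <- snap_site(graph, stations$x, stations$y)$node
  dm <- network_distances(graph, rn, sn)
  rows <- purrr::map(seq_len(nrow(recipients)), function(i) {
    best <- nearest_by_network(dm[i, ], stations$id)
    if (is.null(best)) {
      abort(sprintf("no nursing station reachable for recipient %s",
                    recipients$id[i]))
    }
    tibble(recipient_id = recipients$id[i],
           station_id = best$id, d_station = best$d)
  })
  dplyr::bind_rows(rows)
}

#' Assign a welfare evacuation shelter under the flood-level rule
#'
#' Each recipient evacuates to the nearest shelter by network distance, but
#' shelters standing in a level-3 inundation zone are excluded from candidacy
#' entirely: it is dangerous to travel to any location that floods to level
#' 3, so the recipient instead heads for the nearest shelter whose flood
#' level is 1, 2 or outside the inundation area. When every shelter is
#' level 3 or unreachable the recipient is returned as unassignable
#' (`shelter_id = NA`), never dropped.
#'
#' @param recipients,shelters Site tibbles with `id`, `x`, `y` columns.
#' @param graph A `road_graph`.
#' @param fields A `hazard_fields` object for the level query.
#' @return Tibble: `recipient_id`, `shelter_id`, `d_shelter` (metres),
#'   `shelter_level` (integer, `NA` outside the inundation area).
#' @export
assign_shelter <- function(recipients, shelters, graph, fields) {
  assert_columns(recipients, c("id", "x", "y"), "recipients")
  assert_columns(shelters, c("id", "x", "y"), "shelters")
  if (nrow(shelters) == 0L) abort("at least one shelter is required")
  level <- flood_level_at(fields, shelters$x, shelters$y)
  eligible <- is.na(level) | level <= 2L
  rn <- snap_site(graph, recipients$x, recipients$y)$node
  if (!any(eligible)) {
    return(tibble(recipient_id = recipients$id,
                  shelter_id = NA_character_, d_shelter = NA_real_,
                  shelter_level = NA_integer_))
  }
  cand <- shelters[eligible, , drop = FALSE]
  cand_level <- level[eligible]
  sn <- snap_site(graph, cand$x, cand$y)$node
  dm <- network_distances(graph, rn, sn)
  rows <- purrr::map(seq_len(nrow(recipients)), function(i) {
    best <- nearest_by_network(dm[i, ], cand$id)
    if (is.null(best)) {
      return(tibble(recipient_id = recipients$id[i],
                    shelter_id = NA_character_, d_shelter = NA_real_,
                    shelter_level = NA_integer_))
    }
    tibble(recipient_id = recipients$id[i],
           shelter_id = best$id, d_shelter = best$d,
           shelter_level = cand_level[match(best$id, cand$id)])
  })
  dplyr::bind_rows(rows)
}

#' Compute the per-recipient evacuation time budget
#'
#' The total evacuation time is nurse travel (`d_station / nurse_speed`) plus
#' bed-to-wheelchair transfer plus wheelchair travel
#' (`d_shelter / walk_speed`); the margin is the 30-cm tsunami arrival time
#' at the shelter minus that total. A negative margin means the shelter
#' floods before the evacuation completes - a delayed escape. Recipients with
#' no defined arrival time (outside the 30-cm arrival field) keep an
#' undefined margin and classification. All arithmetic is full precision;
#' rounding happens only on display or when tabulating sensitivity scenarios.
#'
#' @param data Data frame with columns `d_station`, `d_shelter` (metres,
#'   non-negative) and `arrival_min` (minutes or `NA`); an `id` column is
#'   carried through if present, as are any other columns.
#' @param params A [model_parameters()] object.
#' @param arrival_factor Multiplier applied to `arrival_min` (used by the
#'   sensitivity module; default 1).
#' @return An `evac_timing` tibble: the input plus `t_nurse`, `t_transfer`,
#'   `t_walk`, `t_total`, `margin` (all minutes, full precision) and
#'   `delayed` (strict `margin < 0`; `NA` when the margin is undefined).
#' @examples
#' compute_timing(kochi_recipients(), model_parameters())
#' @export
compute_timing <- function(data, params = model_parameters(), arrival_factor = 1) {
  assert_columns(data, c("d_station", "d_shelter", "arrival_min"), "timing input")
  stopifnot(inherits(params, "model_parameters"),
            is_number(arrival_factor), arrival_factor > 0)
  if (any(data$d_station < 0, na.rm = TRUE) || any(data$d_shelter < 0, na.rm = TRUE)) {
    abort("distances must be non-negative")
  }
  out <- as_tibble(data) |>
    dplyr::mutate(
      t_nurse = .data$d_station / params$nurse_speed,
      t_transfer = params$transfer_time,
      t_walk = .data$d_shelter / params$walk_speed,
      t_total = .data$t_nurse + .data$t_transfer + .data$t_walk,
      margin = .data$arrival_min * arrival_factor - .data$t_total,
      delayed = classify_delayed(.data$margin, rounding = "none")
    )
  structure(out, class = c("evac_timing", class(out)),
            params = params, arrival_factor = arrival_factor)
}

#' Classify delayed escapes from margins
#'
#' In the base analysis a recipient is delayed iff the full-precision margin
#' is strictly negative. The sensitivity tables are printed in whole minutes
#' and explicitly count zero cells as delayed, so with `rounding = "minute"`
#' the margin is first rounded to integer minutes (half away from zero) and
#' delayed means `<= 0`. Undefined margins stay undefined.
#'
#' @param margin Numeric vector of margins in minutes (may contain `NA`).
#' @param rounding `"none"` (strict `< 0` on the exact margin) or `"minute"`
#'   (`<= 0` on the integer-rounded margin).
#' @return Logical vector (`NA` where the margin is undefined).
#' @export
classify_delayed <- function(margin, rounding = c("none", "minute")) {
  rounding <- match.arg(rounding)
  if (rounding == "none") margin < 0 else round_display(margin, 0) <= 0
}

#' Run the full assignment-and-timing pipeline on one scenario
#'
#' Convenience wrapper chaining [assign_station()], [assign_shelter()], the
#' arrival-time query at the assigned shelter, and [compute_timing()].
#' Recipients whose shelters lie outside the 30-cm arrival field get an
#' undefined margin; recipients with no eligible shelter are kept as
#' unassignable rows with undefined times.
#'
#' @param recipients,stations,shelters Site tibbles (`id`, `x`, `y`).
#' @param graph A `road_graph`.
#' @param fields A `hazard_fields` object.
#' @param params A [model_parameters()] object.
#' @return An `evac_timing` tibble with assignment columns (`station_id`,
#'   `shelter_id`, `shelter_level`) and the time-budget columns.
#' @export
plan_evacuation <- function(recipients, stations, shelters, graph, fields,
                            params = model_parameters()) {
  st <- assign_station(recipients, stations, graph)
  sh <- assign_shelter(recipients, shelters, graph, fields)
  plan <- dplyr::left_join(st, sh, by = "recipient_id")
  shelter_xy <- plan |>
    dplyr::left_join(dplyr::select(shelters, shelter_id = "id", sx = "x", sy = "y"),
                     by = "shelter_id")
  plan$arrival_min <- NA_real_
  has_shelter <- !is.na(shelter_xy$sx)
  plan$arrival_min[has_shelter] <- arrival_time_at(
    fields, shelter_xy$sx[has_shelter], shelter_xy$sy[has_shelter])
  plan <- dplyr::rename(plan, id = "recipient_id")
  compute_timing(plan, params)
}
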