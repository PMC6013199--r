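#' Scenario multipliers for sensitivity analysis
#'
#' The four tunable quantities of the time budget - nurse travel speed,
#' transfer time, wheelchair travel speed, and tsunami arrival time - are
#' each scaled by a multiplier between 0.5 and 2.0 of the base value. Note
#' the directionality: for the two speeds the adverse end is 0.5 ("slow"),
#' for the two times it is parameter-specific (long transfer = 2.0, short
#' arrival = 0.5).
#'
#' @param nurse_speed,transfer_time,walk_speed,arrival_time Positive
#'   multipliers (base 1).
#' @return A `scenario_factors` list.
#' @export
scenario_factors <- function(nurse_speed = 1, transfer_time = 1,
                             walk_speed = 1, arrival_time = 1) {
  f <- list(nurse_speed = nurse_speed, transfer_time = transfer_time,
            walk_speed = walk_speed, arrival_time = arrival_time)
  for (v in f) if (!is_number(v) || v <= 0) abort("scenario factors must be positive")
  structure(f, class = "scenario_factors")
}

#' Apply scenario multipliers to the model parameters
#'
#' Speeds are multiplied by their factor, the transfer time by its factor;
#' the arrival-time factor cannot be folded into the parameters (arrival is a
#' per-recipient input) and is returned alongside, to be passed to
#' [compute_timing()]'s `arrival_factor`. An undefined arrival time stays
#' undefined under any factor.
#'
#' @param params A [model_parameters()] object.
#' @param factors A [scenario_factors()] object.
#' @return List with `params` (scaled) and `arrival_factor`.
#' @export
apply_factors <- function(params, factors) {
  stopifnot(inherits(params, "model_parameters"),
            inherits(factors, "scenario_factors"))
  list(params = model_parameters(
         nurse_speed = params$nurse_speed * factors$nurse_speed,
         walk_speed = params$walk_speed * factors$walk_speed,
         transfer_time = params$transfer_time * factors$transfer_time),
       arrival_factor = factors$arrival_time)
}

# margins for one factor combination, tabulated in display minutes
scenario_margins <- function(data, params, factors) {
  adj <- apply_factors(params, factors)
  timing <- compute_timing(data, adj$params, arrival_factor = adj$arrival_factor)
  tibble(id = if ("id" %in% names(data)) data$id else as.character(seq_len(nrow(data))),
         margin = timing$margin,
         margin_display = round_display(timing$margin, 0),
         delayed = classify_delayed(timing$margin, rounding = "minute"))
}

#' Count delayed escapes in a tabulated scenario
#'
#' Zero (rounded) margins count as delayed. The percentage denominator is
#' *all* recipients living in the inundation area - including those outside
#' the 30-cm arrival field whose margins are undefined - matching the
#' published tabulation (e.g. 17/21 = 81.0%).
#'
#' @param margin_display Integer-rounded margins (minutes, `NA` = undefined).
#' @param n_total Percentage denominator; defaults to `length(margin_display)`.
#' @return Tibble with `n_delayed` and `pct_delayed` (rounded to 0.1).
#' @export
count_delayed <- function(margin_display, n_total = length(margin_display)) {
  n <- sum(margin_display <= 0, na.rm = TRUE)
  tibble(n_delayed = n,
         pct_delayed = if (n_total > 0) round_display(100 * n / n_total, 1) else 0)
}

new_sensitivity <- function(margins, summary, params, type) {
  structure(list(margins = margins, summary = summary,
                 params = params, type = type),
            class = "evac_sensitivity")
}

#' One-way sensitivity analysis
#'
#' Recomputes every recipient's margin with a single parameter scaled while
#' the other three stay at base, tabulates in whole minutes, and counts
#' delayed escapes (rounded margin <= 0). By default both the adverse and
#' favourable ends (0.5 and 2.0) are run for the chosen parameter.
#'
#' @param data Per-recipient input tibble (see [compute_timing()]), e.g.
#'   [kochi_recipients()].
#' @param params Base [model_parameters()].
#' @param parameter One of `"nurse_speed"`, `"transfer_time"`,
#'   `"walk_speed"`, `"arrival_time"`.
#' @param factors Numeric vector of multipliers to apply (default `c(0.5, 2)`).
#' @return An `evac_sensitivity` object; `$margins` is a long tibble
#'   (`id`, `parameter`, `factor`, `margin`, `margin_display`, `delayed`),
#'   `$summary` one row per factor with delayed counts and percentages.
#' @examples
#' one_way_sensitivity(kochi_recipients(), parameter = "walk_speed")$summary
#' @export
one_way_sensitivity <- function(data, params = model_parameters(),
                                parameter = c("nurse_speed", "transfer_time",
                                              "walk_speed", "arrival_time"),
                                factors = c(0.5, 2)) {
  parameter <- match.arg(parameter)
  stopifnot(is.numeric(factors), all(factors > 0))
  runs <- purrr::map(factors, function(f) {
    fac <- scenario_factors()
    fac[[parameter]] <- f
    class(fac) <- "scenario_factors"
    scenario_margins(data, params, fac) |>
      dplyr::mutate(parameter = parameter, factor = f, .after = "id")
  })
  margins <- dplyr::bind_rows(runs)
  summary <- margins |>
    dplyr::group_by(.data$parameter, .data$factor) |>
    dplyr::summarise(count_delayed(.data$margin_display, n_total = dplyr::n()),
                     .groups = "drop")
  new_sensitivity(margins, summary, params, type = "one_way")
}

#' The 16-scenario multi-way grid, labelled A-P
#'
#' All combinations of the four multipliers at their lower and upper limits,
#' enumerated in the published order: nurse speed outermost (slow 0.5 then
#' fast 2.0), then transfer time (long 2.0, short 0.5), then wheelchair speed
#' (slow 0.5, fast 2.0), then arrival time innermost (short 0.5, long 2.0).
#' Scenario A is the worst case (slow, long, slow, short), P the best (fast,
#' short, fast, long).
#'
#' @return Tibble with columns `scenario` (`"A"`..`"P"`) and the four factors.
#' @export
scenario_grid <- function() {
  g <- expand.grid(f_arrival_time = c(0.5, 2), f_walk_speed = c(0.5, 2),
                   f_transfer_time = c(2, 0.5), f_nurse_speed = c(0.5, 2))
  tibble(scenario = LETTERS[1:16],
         f_nurse_speed = g$f_nurse_speed, f_transfer_time = g$f_transfer_time,
         f_walk_speed = g$f_walk_speed, f_arrival_time = g$f_arrival_time)
}

#' Multi-way sensitivity analysis over scenarios A-P
#'
#' Recomputes all margins under each of the 16 corner combinations of the
#' four parameters (see [scenario_grid()]), tabulates in whole minutes, and
#' counts delayed escapes per scenario (rounded margin <= 0, zeros delayed).
#'
#' @inheritParams one_way_sensitivity
#' @return An `evac_sensitivity` object; `$margins` has one row per recipient
#'   x scenario, `$summary` one row per scenario.
#' @examples
#' multi_way_sensitivity(kochi_recipients())$summary
#' @export
multi_way_sensitivity <- function(data, params = model_parameters()) {
  grid <- scenario_grid()
  runs <- purrr::map(seq_len(nrow(grid)), function(i) {
    fac <- scenario_factors(nurse_speed = grid$f_nurse_speed[i],
                            transfer_time = grid$f_transfer_time[i],
                            walk_speed = grid$f_walk_speed[i],
                            arrival_time = grid$f_arrival_time[i])
    scenario_margins(data, params, fac) |>
      dplyr::mutate(scenario = grid$scenario[i], .after = "id")
  })
  margins <- dplyr::bind_rows(runs)
  summary <- margins |>
    dplyr::group_by(.data$scenario) |>
    dplyr::summarise(count_delayed(.data$margin_display, n_total = dplyr::n()),
                     .groups = "drop") |>
    dplyr::left_join(grid, by = "scenario")
  new_sensitivity(margins, summary, params, type = "multi_way")
}

#' Pivot multi-way margins to the published wide layout
#'
#' @param x An `evac_sensitivity` object from [multi_way_sensitivity()].
#' @return Tibble with one row per recipient and one integer-margin column
#'   per scenario A-P.
#' @export
sensitivity_wide <- function(x) {
  stopifnot(inherits(x, "evac_sensitivity"))
  keys <- if (x$type == "multi_way") "scenario" else c("parameter", "factor")
  x$margins |>
    dplyr::select("id", dplyr::all_of(keys), "margin_display") |>
    tidyr::pivot_wider(names_from = dplyr::all_of(keys),
                       values_from = "margin_display")
}

#' @export
print.evac_sensitivity <- function(x, ...) {
  cat(sprintf("<evac_sensitivity: %s> %d recipients x %d run(s)\n",
              x$type, length(unique(x$margins$id)),
              nrow(x$summary)))
  print(x$summary, ...)
  invisible(x)
}
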