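#' Reproduce the published Kochi study tables from the packaged inputs
#'
#' Runs the whole downstream pipeline on [kochi_recipients()]: base-case
#' timing (written in the published per-recipient layout), the one-way
#' sensitivity analysis for all four parameters at 0.5x and 2.0x, and the
#' 16-scenario multi-way analysis, plus a check summary comparing the key
#' reproduced quantities against the published reference values.
#'
#' @param dir Output directory (created if missing).
#' @param params Base [model_parameters()].
#' @return Invisibly, a list with `timing`, `one_way`, `multi_way` and
#'   `checks`; files `base_timing.csv`, `one_way.csv`, `one_way_counts.csv`,
#'   `multi_way.csv`, `multi_way_counts.csv` and `checks.csv` are written to
#'   `dir`.
#' @export
reproduce_study <- function(dir, params = model_parameters()) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fixture <- kochi_recipients()

  timing <- compute_timing(fixture, params)
  write_timing(timing, file.path(dir, "base_timing.csv"))

  ow <- purrr::map(c("nurse_speed", "transfer_time", "walk_speed", "arrival_time"),
                   function(p) one_way_sensitivity(fixture, params, parameter = p))
  ow_margins <- dplyr::bind_rows(purrr::map(ow, "margins"))
  ow_summary <- dplyr::bind_rows(purrr::map(ow, "summary"))
  readr::write_csv(ow_margins, file.path(dir, "one_way.csv"), na = "n/a")
  readr::write_csv(ow_summary, file.path(dir, "one_way_counts.csv"), na = "n/a")

  mw <- multi_way_sensitivity(fixture, params)
  readr::write_csv(sensitivity_wide(mw), file.path(dir, "multi_way.csv"), na = "n/a")
  readr::write_csv(mw$summary, file.path(dir, "multi_way_counts.csv"), na = "n/a")

  ow_count <- function(p, f) {
    ow_summary$n_delayed[ow_summary$parameter == p & ow_summary$factor == f]
  }
  mw_count <- function(s) mw$summary$n_delayed[mw$summary$scenario == s]
  margin_of <- function(rid) {
    round_display(timing$margin[timing$id == rid], 1)
  }
  checks <- tibble(
    check = c("base margin, recipient 48", "base margin, recipient 47",
              "base total time, recipient 22",
              "delayed @ wheelchair speed x0.5", "delayed @ wheelchair speed x2.0",
              "delayed @ arrival x0.5", "delayed @ arrival x2.0",
              "delayed in worst scenario A", "delayed in best scenario P"),
    value = c(margin_of("48"), margin_of("47"),
              round_display(timing$t_total[timing$id == "22"], 1),
              ow_count("walk_speed", 0.5), ow_count("walk_speed", 2),
              ow_count("arrival_time", 0.5), ow_count("arrival_time", 2),
              mw_count("A"), mw_count("P")),
    reference = c(10.1, 37.5, 148.8, 12, 4, 14, 4, 17, 0))
  checks$pass <- checks$value == checks$reference
  readr::write_csv(checks, file.path(dir, "checks.csv"))

  invisible(list(timing = timing, one_way = ow, multi_way = mw, checks = checks))
}

#' Run the plan stage on scenario files
#'
#' Reads the interchange files written by [write_scenario()] (or prepared by
#' hand in the same formats), builds the road graph, runs assignment and
#' timing, and writes the per-recipient result table plus the evacuation
#' routes.
#'
#' @param input_dir Directory containing `sites.csv`, `roads.geojson`,
#'   `levels.geojson` and `arrival.geojson`.
#' @param output_dir Where to write `timing.csv` and `routes.geojson`
#'   (created if missing).
#' @param params Base [model_parameters()].
#' @param snap_tolerance Endpoint merge tolerance for [build_road_graph()].
#' @return Invisibly, the `evac_timing` tibble.
#' @export
run_plan <- function(input_dir, output_dir, params = model_parameters(),
                     snap_tolerance = 1) {
  sites <- read_sites(file.path(input_dir, "sites.csv"))
  roads <- read_roads_geojson(file.path(input_dir, "roads.geojson"))
  hazard <- read_hazard_geojson(file.path(input_dir, "levels.geojson"),
                                file.path(input_dir, "arrival.geojson"))
  graph <- build_road_graph(roads, snap_tolerance = snap_tolerance)
  split_roles <- split(sites, sites$role)
  timing <- plan_evacuation(split_roles$recipient, split_roles$station,
                            split_roles$shelter, graph, hazard, params)
  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
  write_timing(timing, file.path(output_dir, "timing.csv"))
  routed <- timing[!is.na(timing$shelter_id), ]
  rec_nodes <- snap_site(graph, split_roles$recipient$x, split_roles$recipient$y)
  sh <- split_roles$shelter
  routes <- purrr::map(seq_len(nrow(routed)), function(i) {
    from <- rec_nodes$node[match(routed$id[i], split_roles$recipient$id)]
    to_xy <- sh[match(routed$shelter_id[i], sh$id), ]
    to <- snap_site(graph, to_xy$x, to_xy$y)$node
    shortest_route(graph, from, to)
  })
  write_routes_geojson(routes, graph, file.path(output_dir, "routes.geojson"))
  invisible(timing)
}

# ---- command-line interface ------------------------------------------------
# Thin dispatcher behind inst/cli/evacmargin. Exit codes: 0 success, 1
# usage/config error, 2 data error.

cli_params <- function(opts) {
  model_parameters(
    nurse_speed = opts[["nurse-speed"]] %||% 360,
    walk_speed = opts[["walk-speed"]] %||% 33.3,
    transfer_time = opts[["transfer-time"]] %||% 4.9)
}

#' Command-line entry point
#'
#' Dispatches the subcommands `synth` (write a synthetic scenario), `plan`
#' (assignment + timing on scenario files), `sensitivity` (one-way and
#' multi-way analyses on a timing table) and `reproduce-study`
#' (see [reproduce_study()]). Used by the `inst/cli/evacmargin` script; can
#' be called in-process with an argument vector for testing.
#'
#' @param args Character vector of command-line arguments.
#' @return Integer exit code: 0 success, 1 usage/config error, 2 data error.
#' @export
evacmargin_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: evacmargin <synth|plan|sensitivity|reproduce-study> [options]",
    "  synth           --out DIR [--seed N] [--recipients N] [--stations N] [--shelters N]",
    "  plan            --in DIR --out DIR [--nurse-speed V] [--walk-speed V]",
    "                  [--transfer-time V] [--snap-tolerance V]",
    "  sensitivity     --in TIMING_CSV --out DIR [speed/time flags as above]",
    "  reproduce-study --out DIR",
    sep = "\n")
  if (length(args) == 0L) { message(usage); return(1L) }
  cmd <- args[1L]
  opts <- parse_cli_opts(args[-1L])
  if (is.null(opts)) { message(usage); return(1L) }

  run <- function(expr) {
    tryCatch({ expr; 0L },
             error = function(e) { message("error: ", conditionMessage(e)); 2L })
  }
  switch(cmd,
    synth = {
      if (is.null(opts$out)) { message(usage); return(1L) }
      cfg <- tryCatch(
        scenario_config(seed = opts$seed %||% 1L,
                        n_recipients = opts$recipients %||% 21L,
                        n_stations = opts$stations %||% 9L,
                        n_shelters = opts$shelters %||% 33L),
        error = function(e) { message("config error: ", conditionMessage(e)); NULL })
      if (is.null(cfg)) return(1L)
      run(write_scenario(generate_scenario(cfg), opts$out))
    },
    plan = {
      if (is.null(opts[["in"]]) || is.null(opts$out)) { message(usage); return(1L) }
      run(run_plan(opts[["in"]], opts$out, cli_params(opts),
                   snap_tolerance = opts[["snap-tolerance"]] %||% 1))
    },
    sensitivity = {
      if (is.null(opts[["in"]]) || is.null(opts$out)) { message(usage); return(1L) }
      run({
        data <- read_timing(opts[["in"]])
        if (!dir.exists(opts$out)) dir.create(opts$out, recursive = TRUE)
        params <- cli_params(opts)
        ow <- dplyr::bind_rows(purrr::map(
          c("nurse_speed", "transfer_time", "walk_speed", "arrival_time"),
          function(p) one_way_sensitivity(data, params, parameter = p)$summary))
        readr::write_csv(ow, file.path(opts$out, "one_way_counts.csv"))
        mw <- multi_way_sensitivity(data, params)
        readr::write_csv(sensitivity_wide(mw), file.path(opts$out, "multi_way.csv"),
                         na = "n/a")
        readr::write_csv(mw$summary, file.path(opts$out, "multi_way_counts.csv"))
      })
    },
    `reproduce-study` = {
      if (is.null(opts$out)) { message(usage); return(1L) }
      run(reproduce_study(opts$out))
    },
    { message("unknown command: ", cmd); message(usage); 1L })
}

# --flag value pairs into a named list; numeric-looking values are converted
parse_cli_opts <- function(args) {
  if (length(args) %% 2L != 0L) return(NULL)
  if (length(args) == 0L) return(list())
  keys <- args[seq(1L, length(args), by = 2L)]
  vals <- args[seq(2L, length(args), by = 2L)]
  if (!all(startsWith(keys, "--"))) return(NULL)
  out <- list()
  for (i in seq_along(keys)) {
    v <- vals[i]
    num <- suppressWarnings(as.numeric(v))
    out[[substring(keys[i], 3L)]] <- if (!is.na(num)) num else v
  }
  out
}
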