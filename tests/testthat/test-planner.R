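# Small scenario used across planner tests: a shore-parallel road at y = 0
# with three perpendicular spurs; hazard bands parallel to the coast.
planner_world <- function() {
  roads <- list(
    segment(0, 0, 1000, 0), segment(1000, 0, 2000, 0), segment(2000, 0, 3000, 0),
    segment(0, 0, 0, 1000), segment(0, 1000, 0, 2000),
    segment(1000, 0, 1000, 2000), segment(3000, 0, 3000, 2000)
  )
  graph <- build_road_graph(roads)
  fields <- hazard_fields(
    level_zones = list(
      list(rings = list(matrix(c(-100, -100, 3300, -100, 3300, 700, -100, 700),
                               ncol = 2, byrow = TRUE)), value = 3),
      list(rings = list(matrix(c(-100, 700, 3300, 700, 3300, 1500, -100, 1500),
                               ncol = 2, byrow = TRUE)), value = 2)),
    arrival_zones = list(
      list(rings = list(matrix(c(-100, -100, 3300, -100, 3300, 2100, -100, 2100),
                               ncol = 2, byrow = TRUE)), value = 50)))
  list(graph = graph, fields = fields)
}

test_that("assign_station picks the network-nearest station with id tie-break", {
  w <- planner_world()
  recipients <- tibble::tibble(id = "R1", x = 0, y = 2000)
  stations <- tibble::tibble(id = "ST1", x = 1000, y = 0)
  a <- assign_station(recipients, stations, w$graph)
  expect_equal(a$station_id, "ST1")
  expect_equal(a$d_station, 3000)  # down the spur then along the shore road

  # two stations at exactly equal network distance -> lower id wins
  stations2 <- tibble::tibble(id = c("STB", "STA"), x = c(0, 2000), y = c(0, 0))
  recipients2 <- tibble::tibble(id = "R1", x = 1000, y = 0)
  a2 <- assign_station(recipients2, stations2, w$graph)
  expect_equal(a2$station_id, "STA")
  expect_equal(a2$d_station, 1000)
})

test_that("assign_station matches an exhaustive per-station minimum", {
  withr::local_seed(5)
  scn <- generate_scenario(scenario_config(seed = 5, extent = c(2000, 2000),
                                           road_spacing = 250, n_recipients = 5,
                                           n_stations = 4, n_shelters = 6))
  sp_ <- split(scn$sites, scn$sites$role)
  a <- assign_station(sp_$recipient, sp_$station, scn$graph)
  for (i in seq_len(nrow(sp_$recipient))) {
    rn <- snap_site(scn$graph, sp_$recipient$x[i], sp_$recipient$y[i])$node
    d <- vapply(seq_len(nrow(sp_$station)), function(j) {
      sn <- snap_site(scn$graph, sp_$station$x[j], sp_$station$y[j])$node
      shortest_route(scn$graph, rn, sn)$length_m
    }, numeric(1))
    expect_equal(a$d_station[i], min(d))
  }
})

test_that("assign_shelter excludes level-3 shelters entirely", {
  w <- planner_world()
  recipients <- tibble::tibble(id = "R1", x = 0, y = 0)
  # nearest shelter (400 m) is in the level-3 band, next (1000 m) in level 2
  shelters <- tibble::tibble(id = c("SH_near", "SH_far"),
                             x = c(0, 0), y = c(400, 1000))
  a <- assign_shelter(recipients, shelters, w$graph, w$fields)
  expect_equal(a$shelter_id, "SH_far")
  expect_equal(a$d_shelter, 1000)
  expect_equal(a$shelter_level, 2L)

  # a single eligible shelter is chosen even when distant
  a2 <- assign_shelter(recipients, shelters[2, ], w$graph, w$fields)
  expect_equal(a2$shelter_id, "SH_far")

  # every shelter at level 3 -> unassignable, id carried, no error
  a3 <- assign_shelter(recipients, shelters[1, ], w$graph, w$fields)
  expect_equal(a3$recipient_id, "R1")
  expect_true(is.na(a3$shelter_id))
  expect_true(is.na(a3$d_shelter))
})

test_that("assign_shelter never returns a level-3 shelter across synthetic scenarios", {
  for (seed in 1:20) {
    scn <- generate_scenario(scenario_config(
      seed = seed, extent = c(2500, 2500), road_spacing = 250,
      n_recipients = 4, n_stations = 3, n_shelters = 8))
    sp_ <- split(scn$sites, scn$sites$role)
    a <- assign_shelter(sp_$recipient, sp_$shelter, scn$graph, scn$hazard)
    expect_true(all(is.na(a$shelter_level) | a$shelter_level <= 2L))
    picked <- sp_$shelter[match(a$shelter_id, sp_$shelter$id), ]
    lv <- flood_level_at(scn$hazard, picked$x, picked$y)
    expect_true(all(is.na(lv) | lv <= 2L))
  }
})

test_that("compute_timing reproduces the published worked examples", {
  p <- model_parameters()
  # recipient 48: 1,748 m nurse leg, 1,336 m wheelchair leg, 60-min deadline
  t48 <- compute_timing(
    tibble::tibble(d_station = 1748, d_shelter = 1336, arrival_min = 60), p)
  expect_equal(round_display(t48$t_nurse, 1), 4.9)
  expect_equal(round_display(t48$t_walk, 1), 40.1)
  expect_equal(round_display(t48$t_total, 1), 49.9)
  expect_equal(round_display(t48$margin, 1), 10.1)
  expect_false(t48$delayed)

  # transfer-only degenerate case
  t0 <- compute_timing(
    tibble::tibble(d_station = 0, d_shelter = 0, arrival_min = 60), p)
  expect_equal(t0$t_total, 4.9)
  expect_equal(t0$margin, 55.1)

  # recipient 22: longest legs in the study area
  t22 <- compute_timing(
    tibble::tibble(d_station = 2694, d_shelter = 4543, arrival_min = 60), p)
  expect_equal(round_display(t22$t_total, 1), 148.8)

  expect_error(compute_timing(
    tibble::tibble(d_station = -1, d_shelter = 0, arrival_min = 60), p),
    "non-negative")
})

test_that("the time-budget identity and monotonicities hold", {
  withr::local_seed(21)
  d1 <- runif(50, 0, 5000); d2 <- runif(50, 0, 5000); arr <- runif(50, 10, 120)
  data <- tibble::tibble(d_station = d1, d_shelter = d2, arrival_min = arr)
  p <- model_parameters()
  t <- compute_timing(data, p)
  expect_equal(t$t_total, t$t_nurse + t$t_transfer + t$t_walk, tolerance = 1e-12)
  expect_equal(t$margin, t$arrival_min - t$t_total, tolerance = 1e-12)
  # halving the wheelchair speed exactly doubles the walk time
  t_half <- compute_timing(data, model_parameters(walk_speed = p$walk_speed / 2))
  expect_equal(t_half$t_walk, 2 * t$t_walk, tolerance = 1e-12)
  # margin strictly decreasing in each distance, increasing in arrival
  t_more <- compute_timing(dplyr::mutate(data, d_shelter = d_shelter + 1), p)
  expect_true(all(t_more$margin < t$margin))
  t_later <- compute_timing(dplyr::mutate(data, arrival_min = arrival_min + 1), p)
  expect_true(all(t_later$margin > t$margin))
})

test_that("classify_delayed applies the strict base rule and the zero-counts display rule", {
  expect_true(classify_delayed(-13.3))
  expect_false(classify_delayed(0))         # exact zero not delayed at full precision
  expect_true(is.na(classify_delayed(NA_real_)))
  # display rule: integer-rounded zeros count as delayed
  expect_true(classify_delayed(0.38, rounding = "minute"))   # rounds to 0
  expect_true(classify_delayed(-0.2, rounding = "minute"))
  expect_false(classify_delayed(0.51, rounding = "minute"))  # rounds to 1
})

test_that("plan_evacuation chains assignment, hazard lookup and timing", {
  w <- planner_world()
  recipients <- tibble::tibble(id = c("R1", "R2"), x = c(0, 3000), y = c(0, 2050))
  stations <- tibble::tibble(id = "ST1", x = 1000, y = 0)
  shelters <- tibble::tibble(id = c("SH1", "SH2"), x = c(0, 3000), y = c(1000, 2000))
  t <- plan_evacuation(recipients, stations, shelters, w$graph, w$fields)
  expect_s3_class(t, "evac_timing")
  expect_equal(t$shelter_id, c("SH1", "SH2"))
  # R1's shelter sits inside the 50-min arrival zone; R2's shelter (y=2000)
  # is inside too, but R2 snaps to the far end of the spur
  expect_equal(t$arrival_min, c(50, 50))
  expect_equal(t$t_total, t$t_nurse + t$t_transfer + t$t_walk)
  g <- glance(t)
  expect_equal(g$n_recipients, 2L)
  td <- tidy(t)
  expect_false(inherits(td, "evac_timing"))
})
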