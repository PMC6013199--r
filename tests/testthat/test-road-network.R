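test_that("build_road_graph merges snapped endpoints and weights edges by arc length", {
  # two polylines sharing an endpoint exactly
  g <- build_road_graph(list(segment(0, 0, 100, 0), segment(100, 0, 100, 80)))
  expect_equal(nrow(g$nodes), 3L)
  expect_equal(nrow(g$edges), 2L)
  expect_equal(sort(g$edges$length_m), c(80, 100))

  # endpoints 0.5 m apart with tolerance 1 merge into one node
  g2 <- build_road_graph(list(segment(0, 0, 100, 0), segment(100.5, 0, 200, 0)),
                         snap_tolerance = 1)
  expect_equal(nrow(g2$nodes), 3L)

  # square of four 100-m segments
  sq <- build_road_graph(list(segment(0, 0, 100, 0), segment(100, 0, 100, 100),
                              segment(100, 100, 0, 100), segment(0, 100, 0, 0)))
  expect_equal(nrow(sq$nodes), 4L)
  expect_equal(sq$edges$length_m, rep(100, 4))

  # arc length through interior vertices, not endpoint chord
  bent <- matrix(c(0, 0, 30, 40, 60, 0), ncol = 2, byrow = TRUE)
  gb <- build_road_graph(list(bent))
  expect_equal(gb$edges$length_m, 100)
  expect_equal(nrow(gb$nodes), 2L)
})

test_that("degenerate polylines are dropped with a warning, not an error", {
  expect_warning(g <- build_road_graph(list(segment(0, 0, 0, 0),
                                            segment(0, 0, 100, 0))),
                 "zero-length")
  expect_equal(nrow(g$edges), 1L)
  # endpoints snapping together would create a self-loop; dropped
  expect_warning(g2 <- build_road_graph(list(segment(0, 0, 0.4, 0)),
                                        snap_tolerance = 1),
                 "self-loop")
  expect_equal(nrow(g2$edges), 0L)
})

test_that("snap_site returns the nearest node with id tie-breaking", {
  g <- build_road_graph(list(segment(0, 0, 100, 0)))
  # coincident with node n1
  expect_equal(snap_site(g, 0, 0)$node, "n1")
  expect_equal(snap_site(g, 0, 0)$offset_m, 0)
  # equidistant between n1 and n2 -> lexicographically smaller id
  s <- snap_site(g, 50, 10)
  expect_equal(s$node, "n1")
  expect_equal(s$offset_m, sqrt(50^2 + 10^2))
  expect_error(snap_site(build_road_graph(list()), 0, 0), "empty")
})

test_that("snap_site agrees with an exhaustive nearest-node scan", {
  withr::local_seed(11)
  for (rep in 1:50) {
    pts <- matrix(runif(20, 0, 100), ncol = 2)
    polys <- lapply(seq_len(nrow(pts) / 2), function(i) {
      pts[c(2 * i - 1, 2 * i), , drop = FALSE]
    })
    g <- suppressWarnings(build_road_graph(polys, snap_tolerance = 0))
    px <- runif(1, 0, 100); py <- runif(1, 0, 100)
    expect_equal(snap_site(g, px, py)$node, scan_nearest(g$nodes, px, py)$node)
  }
})

test_that("shortest_route handles identity, forced choices, and unreachable pairs", {
  g <- build_road_graph(list(segment(0, 0, 100, 0)))
  same <- shortest_route(g, "n1", "n1")
  expect_true(same$reachable)
  expect_equal(same$length_m, 0)
  expect_equal(same$nodes, "n1")

  # 3-4-5 triangle: direct A-C edge (5) ties the arithmetic, detour is 7
  tri <- build_road_graph(list(segment(0, 0, 3, 0),      # A-B, 3
                               segment(3, 0, 3, 4),      # B-C, 4
                               segment(0, 0, 3, 4)))     # A-C, 5
  r <- shortest_route(tri, "n1", "n3")
  expect_equal(r$length_m, 5)
  expect_equal(r$nodes, c("n1", "n3"))

  # disconnected components yield an explicit unreachable result
  disc <- build_road_graph(list(segment(0, 0, 100, 0), segment(1000, 0, 1100, 0)))
  u <- shortest_route(disc, "n1", "n3")
  expect_false(u$reachable)
  expect_equal(u$length_m, Inf)
  expect_length(u$nodes, 0L)
  expect_error(shortest_route(disc, "n1", "zz"), "unknown node")
})

test_that("equal-length shortest paths break ties lexicographically", {
  # two equal 200-m routes n1->n4: via n2 or via n3; n1,n2,n4 < n1,n3,n4
  g <- build_road_graph(list(segment(0, 0, 100, 0),     # n1-n2
                             segment(0, 0, 0, 100),     # n1-n3
                             segment(100, 0, 100, 100), # n2-n4... constructed below
                             segment(0, 100, 100, 100)))
  r <- shortest_route(g, "n1", "n4")
  expect_equal(r$length_m, 200)
  expect_equal(r$nodes, c("n1", "n2", "n4"))
})

test_that("routing matches brute-force path enumeration on random small graphs", {
  withr::local_seed(42)
  n_cases <- 1000
  for (case in seq_len(n_cases)) {
    n <- sample(4:8, 1)
    xy <- matrix(runif(2 * n, 0, 100), ncol = 2)
    pairs <- utils::combn(n, 2)
    m <- sample(n:(ncol(pairs)), 1)
    take <- sample(ncol(pairs), min(m, ncol(pairs)))
    polys <- lapply(take, function(k) xy[pairs[, k], , drop = FALSE])
    g <- suppressWarnings(build_road_graph(polys, snap_tolerance = 0))
    ids <- g$nodes$node
    ft <- sample(ids, 2)
    edges <- data.frame(from = g$edges$from, to = g$edges$to, w = g$edges$length_m)
    expected <- enumerate_shortest(edges, ft[1], ft[2])
    got <- shortest_route(g, ft[1], ft[2])
    expect_equal(got$length_m, expected, tolerance = 1e-9)
    if (is.finite(expected)) {
      # route is a real walk through adjacent nodes with consistent length
      expect_true(got$reachable)
      expect_equal(got$nodes[1], ft[1])
      expect_equal(got$nodes[length(got$nodes)], ft[2])
    }
  }
})

test_that("network distance dominates straight-line distance and obeys the triangle inequality", {
  withr::local_seed(7)
  scn <- generate_scenario(scenario_config(seed = 7, extent = c(2000, 2000),
                                           road_spacing = 400, n_recipients = 3,
                                           n_stations = 2, n_shelters = 4))
  g <- scn$graph
  ids <- g$nodes$node
  d <- network_distances(g, ids, ids)
  for (rep in 1:200) {
    abc <- sample(ids, 3)
    i <- match(abc, ids)
    straight <- euclid_dist <- sqrt((g$nodes$x[i[1]] - g$nodes$x[i[2]])^2 +
                                    (g$nodes$y[i[1]] - g$nodes$y[i[2]])^2)
    expect_gte(d[i[1], i[2]] + 1e-9, straight)
    expect_lte(d[i[1], i[2]], d[i[1], i[3]] + d[i[3], i[2]] + 1e-9)
  }
})
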