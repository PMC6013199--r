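#' Build a routable road graph from polylines
#'
#' Re-creates the road-graph step of the original GIS workflow: every
#' polyline becomes one undirected edge weighted by its Euclidean arc length,
#' and polyline endpoints closer than `snap_tolerance` are merged into a
#' single node (road data rarely shares endpoints exactly). Interior vertices
#' contribute geometry and length but are not routable nodes.
#'
#' Zero-length polylines are dropped with a warning, as are polylines whose
#' two endpoints snap to the same node (self-loops cannot be part of a
#' shortest path).
#'
#' @param polylines List of two-column coordinate matrices (metres), e.g. from
#'   [read_roads_geojson()].
#' @param snap_tolerance Endpoint merge distance in metres (default 1).
#' @return A `road_graph`: list with `graph` (weighted undirected
#'   [igraph][igraph::igraph-package] graph), `nodes` (tibble `node`, `x`,
#'   `y`) and `edges` (tibble `from`, `to`, `length_m`, `geometry`).
#' @export
build_road_graph <- function(polylines, snap_tolerance = 1) {
  stopifnot(is.list(polylines), is_number(snap_tolerance), snap_tolerance >= 0)
  nx <- ny <- numeric(0)

  snap_node <- function(x, y) {
    if (length(nx) > 0L) {
      d2 <- (nx - x)^2 + (ny - y)^2
      j <- which.min(d2)
      if (d2[j] <= snap_tolerance^2) return(j)
    }
    nx[length(nx) + 1L] <<- x
    ny[length(ny) + 1L] <<- y
    length(nx)
  }

  from <- to <- integer(0)
  len <- numeric(0)
  geom <- list()
  for (k in seq_along(polylines)) {
    m <- polylines[[k]]
    if (!is.matrix(m) || nrow(m) < 2L || ncol(m) != 2L) {
      abort(sprintf("polyline %d is not a matrix with >= 2 points and 2 columns", k))
    }
    L <- polyline_length(m)
    if (L <= 0) {
      warn(sprintf("dropping zero-length polyline %d", k))
      next
    }
    a <- snap_node(m[1L, 1L], m[1L, 2L])
    b <- snap_node(m[nrow(m), 1L], m[nrow(m), 2L])
    if (a == b) {
      warn(sprintf("dropping polyline %d: endpoints snap to one node (self-loop)", k))
      next
    }
    from <- c(from, a); to <- c(to, b)
    len <- c(len, L)
    geom[[length(geom) + 1L]] <- m
  }

  node_id <- sprintf("n%d", seq_along(nx))
  g <- igraph::make_empty_graph(n = length(nx), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = node_id)
  if (length(from) > 0L) {
    g <- igraph::add_edges(g, rbind(from, to))
    g <- igraph::set_edge_attr(g, "weight", value = len)
  }
  structure(
    list(graph = g,
         nodes = tibble(node = node_id, x = nx, y = ny),
         edges = tibble(from = node_id[from], to = node_id[to],
                        length_m = len, geometry = geom)),
    class = "road_graph")
}

#' @export
print.road_graph <- function(x, ...) {
  cat(sprintf("<road_graph> %d nodes, %d edges, total length %.0f m\n",
              nrow(x$nodes), nrow(x$edges), sum(x$edges$length_m)))
  invisible(x)
}

#' Snap an off-network site to its nearest graph node
#'
#' Sites (homes, stations, shelters) rarely sit exactly on a road node; each
#' is routed from the node minimising Euclidean distance. The site-to-node
#' offset is reported as a diagnostic but never added to route distances (the
#' published distances are route distances only). Ties are broken by the
#' lexicographically smallest node id.
#'
#' @param graph A `road_graph`.
#' @param x,y Site coordinates (metres); vectors of equal length snap several
#'   sites at once.
#' @return Tibble with one row per site: `node`, `offset_m`.
#' @export
snap_site <- function(graph, x, y) {
  stopifnot(inherits(graph, "road_graph"), length(x) == length(y))
  if (nrow(graph$nodes) == 0L) abort("cannot snap to an empty road graph")
  ord_id <- order(graph$nodes$node)
  res <- purrr::map2(x, y, function(px, py) {
    d <- euclid(graph$nodes$x, graph$nodes$y, px, py)
    best <- ord_id[d[ord_id] == min(d)][1L]  # tie -> smallest node id
    list(node = graph$nodes$node[best], offset_m = d[best])
  })
  tibble(node = purrr::map_chr(res, "node"),
         offset_m = purrr::map_dbl(res, "offset_m"))
}

#' Shortest route between two graph nodes
#'
#' Dijkstra shortest path on arc-length weights. Among equal-length minimal
#' paths the lexicographically smallest node-id sequence is returned, so the
#' result is deterministic. A disconnected pair yields an explicit
#' unreachable result, never an error.
#'
#' @param graph A `road_graph`.
#' @param from,to Node ids.
#' @return A list: `reachable` (logical), `length_m` (`Inf` when unreachable)
#'   and `nodes` (character vector of the node sequence, empty when
#'   unreachable).
#' @export
shortest_route <- function(graph, from, to) {
  stopifnot(inherits(graph, "road_graph"))
  nodes <- graph$nodes$node
  if (!from %in% nodes || !to %in% nodes) {
    abort(sprintf("unknown node id: %s",
                  paste(setdiff(c(from, to), nodes), collapse = ", ")))
  }
  if (identical(from, to)) {
    return(list(reachable = TRUE, length_m = 0, nodes = from))
  }
  suppressWarnings(
    asp <- igraph::all_shortest_paths(graph$graph, from = from, to = to,
                                      weights = NULL)$vpaths
  )
  if (length(asp) == 0L) {
    return(list(reachable = FALSE, length_m = Inf, nodes = character(0)))
  }
  seqs <- lapply(asp, function(p) igraph::as_ids(p))
  # lexicographic tie-break on the node-id sequence
  best <- seqs[[1L]]
  for (s in seqs[-1L]) if (seq_less(s, best)) best <- s
  list(reachable = TRUE,
       length_m = as.numeric(igraph::distances(graph$graph, v = from, to = to,
                                               weights = NULL)[1L, 1L]),
       nodes = best)
}

# lexicographic comparison of two character sequences
seq_less <- function(a, b) {
  n <- min(length(a), length(b))
  for (i in seq_len(n)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  length(a) < length(b)
}

#' Network distances between node sets
#'
#' Shortest-path distance matrix on arc-length weights; `Inf` marks
#' disconnected pairs.
#'
#' @param graph A `road_graph`.
#' @param from,to Character vectors of node ids.
#' @return Numeric matrix of distances in metres, `from` by `to`.
#' @export
network_distances <- function(graph, from, to) {
  stopifnot(inherits(graph, "road_graph"))
  uf <- unique(from); ut <- unique(to)
  d <- igraph::distances(graph$graph, v = uf, to = ut, weights = NULL,
                         algorithm = "dijkstra")
  d <- d[match(from, uf), match(to, ut), drop = FALSE]
  dimnames(d) <- list(from, to)
  d
}
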