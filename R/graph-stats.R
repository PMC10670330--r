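#' Degree of a node
#'
#' Number of neighbours of `v` in the simple graph `g`.
#'
#' @param g An undirected igraph graph with named vertices.
#' @param v Node identifier (character) or vector of identifiers.
#' @return Named integer vector of degrees.
#' @export
node_degree <- function(g, v) {
  check_graph(g); g <- ensure_names(g)
  check_vertex(g, v)
  d <- igraph::degree(g, v = as.character(v))
  storage.mode(d) <- "integer"
  d
}

#' Neighbour set of a node
#'
#' @inheritParams node_degree
#' @param v A single node identifier.
#' @return Character vector of adjacent node names (never contains `v`).
#' @export
node_neighbors <- function(g, v) {
  check_graph(g); g <- ensure_names(g)
  stopifnot(length(v) == 1L)
  check_vertex(g, v)
  igraph::neighbors(g, as.character(v))$name
}

#' Local clustering coefficient
#'
#' Fraction of a node's neighbour pairs that are themselves connected:
#' \eqn{2 e_v / (k_v (k_v - 1))} where \eqn{e_v} counts edges among the
#' neighbours of \eqn{v}. Nodes of degree < 2 get 0 by convention, keeping
#' the coefficient total over all nodes (and over all common neighbours,
#' which always have degree >= 2 anyway).
#'
#' @inheritParams node_degree
#' @param v Node identifier(s); `NULL` (default) returns all nodes.
#' @return Named numeric vector of coefficients in \[0, 1\].
#' @export
local_clustering <- function(g, v = NULL) {
  check_graph(g); g <- ensure_names(g)
  if (!is.null(v)) check_vertex(g, v)
  vids <- if (is.null(v)) igraph::V(g) else as.character(v)
  cc <- igraph::transitivity(g, type = "local", vids = vids, isolates = "zero")
  names(cc) <- if (is.null(v)) igraph::V(g)$name else as.character(v)
  cc
}

#' Breadth-first shortest-path distances from one node
#'
#' Unit-weight hop counts from `source` to every node it can reach.
#' Unreachable nodes are absent from the result; the distance to `source`
#' itself is 0.
#'
#' @inheritParams node_degree
#' @param source A single node identifier.
#' @return Named integer vector of distances over reachable nodes only.
#' @export
shortest_path_lengths <- function(g, source) {
  check_graph(g); g <- ensure_names(g)
  stopifnot(length(source) == 1L)
  check_vertex(g, source, "source")
  d <- igraph::distances(g, v = as.character(source), weights = NA)[1L, ]
  d <- d[is.finite(d)]
  storage.mode(d) <- "integer"
  d
}

#' Closeness centrality, component-scaled
#'
#' On a connected graph this is the classical closeness
#' \eqn{C_v = (n - 1) / \sum_{j \ne v} d_{vj}}. On a disconnected graph the
#' Wasserman–Faust component scaling is applied: a node reaching
#' \eqn{r_v < n - 1} others gets
#' \eqn{(r_v / (n - 1)) \cdot (r_v / \sum_{j\,reachable} d_{vj})}, which
#' reduces exactly to the classical form when the graph is connected and
#' keeps the score total on the fragmented training graphs produced by edge
#' holdout. Isolated nodes get 0.
#'
#' @inheritParams node_degree
#' @param v Node identifier(s); `NULL` (default) returns all nodes.
#' @return Named numeric vector of non-negative closeness values.
#' @export
closeness_centrality <- function(g, v = NULL) {
  check_graph(g); g <- ensure_names(g)
  if (!is.null(v)) check_vertex(g, v)
  n <- igraph::vcount(g)
  vids <- if (is.null(v)) igraph::V(g)$name else as.character(v)
  if (n < 2L) {
    out <- rep(0, length(vids)); names(out) <- vids
    return(out)
  }
  D <- igraph::distances(g, v = vids, weights = NA)
  out <- apply(D, 1L, function(row) {
    row <- row[is.finite(row)]
    tot <- sum(row)             # self-distance 0 contributes nothing
    r <- length(row) - 1L       # reachable others
    if (r <= 0L || tot == 0) return(0)
    (r / (n - 1)) * (r / tot)
  })
  names(out) <- vids
  out
}

#' Pair closeness of two nodes
#'
#' The node-pair feature \eqn{C_{u,v} = C_u + C_v}: the sum of the two
#' endpoints' (component-scaled) closeness centralities.
#'
#' @inheritParams node_degree
#' @param u,v Distinct node identifiers.
#' @return A single non-negative number.
#' @export
pair_closeness <- function(g, u, v) {
  if (identical(as.character(u), as.character(v))) {
    stop("pair closeness requires two distinct nodes", call. = FALSE)
  }
  cl <- closeness_centrality(g, c(u, v))
  unname(cl[1L] + cl[2L])
}

#' Network-level summary statistics
#'
#' Computes once, for reuse by the scorers: node and edge counts, density,
#' the average local clustering coefficient (mean over all nodes, degree-<2
#' nodes counting 0), and the average shortest path length (mean over
#' unordered *reachable* pairs only, so it stays finite on disconnected
#' graphs; 0 when fewer than one reachable pair exists).
#'
#' @inheritParams node_degree
#' @return An object of class `graph_stats`: a list with elements `n`, `m`,
#'   `density`, `avg_clustering`, `avg_shortest_path`.
#' @examples
#' g <- generate_graph("complete", n = 4)
#' graph_stats(g)  # density 1, clustering 1, mean distance 1
#' @export
graph_stats <- function(g) {
  check_graph(g); g <- ensure_names(g)
  n <- igraph::vcount(g)
  if (n == 0L) stop("graph_stats() requires a non-empty graph", call. = FALSE)
  m <- igraph::ecount(g)
  density <- if (n >= 2L) 2 * m / (n * (n - 1)) else 0
  avg_cc <- mean(local_clustering(g))
  d <- igraph::mean_distance(g, directed = FALSE, unconnected = TRUE)
  if (!is.finite(d)) d <- 0
  structure(
    list(n = n, m = m, density = density,
         avg_clustering = avg_cc, avg_shortest_path = d),
    class = "graph_stats"
  )
}

#' @export
print.graph_stats <- function(x, ...) {
  cat(sprintf(
    "Graph: %d nodes, %d edges, density %.4g\n  avg clustering <c> = %.4f, avg shortest path <d> = %.4f\n",
    x$n, x$m, x$density, x$avg_clustering, x$avg_shortest_path))
  invisible(x)
}
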