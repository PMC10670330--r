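#' Generate a synthetic test graph
#'
#' Seed-deterministic simple undirected graphs from the standard random
#' models, plus small deterministic fixtures. All vertices are named
#' `"1" ... "n"` so generated graphs flow through the same string-labelled
#' pipeline as graphs read from edge lists.
#'
#' Models:
#' \describe{
#'   \item{`erdos_renyi`}{G(n, p): each of the n(n-1)/2 pairs is an edge
#'     independently with probability `p`.}
#'   \item{`barabasi_albert`}{Preferential-attachment growth: the graph
#'     starts from a single node and each new node attaches `m_attach`
#'     edges to existing nodes with probability proportional to degree
#'     (early nodes attach fewer when fewer targets exist, so the edge
#'     count is `sum(pmin(m_attach, 1:(n-1)))`). No multi-edges.}
#'   \item{`watts_strogatz`}{Ring lattice of degree `k_ring` (must be even)
#'     with each edge rewired independently with probability `p_rewire`;
#'     loops and duplicate edges are removed.}
#'   \item{`complete`, `path`, `star`, `two_triangles`}{Deterministic
#'     fixtures; `seed` is ignored. The star's hub is node `"1"`;
#'     `two_triangles` is two disjoint triangles on 6 nodes (`n` ignored).}
#' }
#'
#' @param model One of `"erdos_renyi"`, `"barabasi_albert"`,
#'   `"watts_strogatz"`, `"complete"`, `"path"`, `"star"`,
#'   `"two_triangles"`.
#' @param n Number of nodes (>= 2).
#' @param p Edge probability for `erdos_renyi`.
#' @param m_attach Edges attached per new node for `barabasi_albert`
#'   (1 <= `m_attach` < `n`).
#' @param k_ring Even lattice degree for `watts_strogatz` (< `n`).
#' @param p_rewire Rewiring probability for `watts_strogatz`.
#' @param seed Integer seed for the random models.
#' @return An undirected simple igraph graph with named vertices.
#' @examples
#' generate_graph("complete", n = 4)
#' generate_graph("watts_strogatz", n = 50, k_ring = 6, p_rewire = 0.1,
#'                seed = 1)
#' @export
generate_graph <- function(model = c("erdos_renyi", "barabasi_albert",
                                     "watts_strogatz", "complete", "path",
                                     "star", "two_triangles"),
                           n = NULL, p = NULL, m_attach = NULL,
                           k_ring = NULL, p_rewire = NULL, seed = NULL) {
  model <- match.arg(model)
  if (model != "two_triangles") {
    if (is.null(n) || n < 2L) stop("`n` must be at least 2", call. = FALSE)
    n <- as.integer(n)
  }
  g <- switch(model,
    erdos_renyi = {
      if (is.null(p) || p < 0 || p > 1) {
        stop("`p` must be a probability in [0, 1]", call. = FALSE)
      }
      with_seed(seed, igraph::sample_gnp(n, p))
    },
    barabasi_albert = {
      if (is.null(m_attach) || m_attach < 1L || m_attach >= n) {
        stop("`m_attach` must satisfy 1 <= m_attach < n", call. = FALSE)
      }
      with_seed(seed, igraph::sample_pa(n, m = m_attach, directed = FALSE))
    },
    watts_strogatz = {
      if (is.null(k_ring) || k_ring %% 2L != 0L || k_ring >= n) {
        stop("`k_ring` must be even and smaller than n", call. = FALSE)
      }
      if (is.null(p_rewire) || p_rewire < 0 || p_rewire > 1) {
        stop("`p_rewire` must be a probability in [0, 1]", call. = FALSE)
      }
      with_seed(seed, igraph::sample_smallworld(1, n, nei = k_ring %/% 2L,
                                                p = p_rewire))
    },
    complete = igraph::make_full_graph(n),
    path = igraph::make_ring(n, circular = FALSE),
    star = igraph::make_star(n, mode = "undirected", center = 1L),
    two_triangles = igraph::graph_from_edgelist(
      cbind(c("1", "2", "3", "4", "5", "6"),
            c("2", "3", "1", "5", "6", "4")), directed = FALSE)
  )
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  ensure_names(g)
}

#' Small labelled closeness/clustering illustration graphs
#'
#' Two tiny graphs contrasting clustering with closeness: variant `"a"` is
#' the chain a–b–c (all local clustering coefficients 0; the middle node
#' has the highest closeness), variant `"b"` is the triangle a, b, c plus a
#' pendant edge a–d (the triangle members have positive clustering; a and d
#' are directly connected).
#'
#' @param variant `"a"` or `"b"`.
#' @return An undirected igraph graph with named vertices.
#' @export
fixture_figure1 <- function(variant = c("a", "b")) {
  variant <- match.arg(variant)
  el <- if (variant == "a") {
    cbind(c("a", "b"), c("b", "c"))
  } else {
    cbind(c("a", "b", "c", "a"), c("b", "c", "a", "d"))
  }
  igraph::graph_from_edgelist(el, directed = FALSE)
}
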