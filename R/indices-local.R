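# Per-pair similarity scorers. Each takes the graph plus two distinct nodes
# and returns one non-negative score; the vectorised table route lives in
# score_index(). Common-neighbour based indices all reduce to a sum over
# z in N(u) n N(v).

common_neighbor_names <- function(g, u, v) {
  stopifnot(length(u) == 1L, length(v) == 1L)
  check_graph(g); g <- ensure_names(g)
  check_vertex(g, c(u, v))
  if (identical(as.character(u), as.character(v))) {
    stop("similarity scores are defined for distinct nodes only", call. = FALSE)
  }
  nu <- igraph::neighbors(g, as.character(u))$name
  nv <- igraph::neighbors(g, as.character(v))$name
  nu[nu %in% nv]
}

#' Common-neighbours index
#'
#' \eqn{S_{uv} = |\Gamma_u \cap \Gamma_v|}: the number of shared neighbours.
#'
#' @param g An undirected igraph graph with named vertices.
#' @param u,v Distinct node identifiers.
#' @return A single non-negative score.
#' @family similarity indices
#' @export
cn_score <- function(g, u, v) {
  length(common_neighbor_names(g, u, v))
}

#' Adamic–Adar index
#'
#' \eqn{S_{uv} = \sum_{z \in \Gamma_u \cap \Gamma_v} 1 / \ln k_z} (natural
#' logarithm). Common neighbours always have degree >= 2, so every term is
#' finite.
#'
#' @inheritParams cn_score
#' @return A single non-negative score.
#' @family similarity indices
#' @export
aa_score <- function(g, u, v) {
  z <- common_neighbor_names(g, u, v)
  if (length(z) == 0L) return(0)
  sum(1 / log(igraph::degree(g, z)))
}

#' Resource-allocation index
#'
#' \eqn{S_{uv} = \sum_{z \in \Gamma_u \cap \Gamma_v} 1 / k_z}.
#'
#' @inheritParams cn_score
#' @return A single non-negative score.
#' @family similarity indices
#' @export
ra_score <- function(g, u, v) {
  z <- common_neighbor_names(g, u, v)
  if (length(z) == 0L) return(0)
  sum(1 / igraph::degree(g, z))
}

#' Preferential-attachment index
#'
#' \eqn{S_{uv} = k_u \cdot k_v}.
#'
#' @inheritParams cn_score
#' @return A single non-negative score.
#' @family similarity indices
#' @export
pa_score <- function(g, u, v) {
  check_graph(g); g <- ensure_names(g)
  check_vertex(g, c(u, v))
  unname(igraph::degree(g, as.character(u)) *
           igraph::degree(g, as.character(v)))
}

#' Clustering-coefficient link-prediction (CCLP) index
#'
#' \eqn{S_{uv} = \sum_{z \in \Gamma_u \cap \Gamma_v} CC_z}: the summed local
#' clustering coefficients of the common neighbours.
#'
#' @inheritParams cn_score
#' @return A single non-negative score.
#' @family similarity indices
#' @export
cclp_score <- function(g, u, v) {
  z <- common_neighbor_names(g, u, v)
  if (length(z) == 0L) return(0)
  sum(local_clustering(g, z))
}

#' CN2D index
#'
#' Common neighbours augmented by a degree-normalised second-order term:
#' \deqn{S_{uv} = |\Gamma_u \cap \Gamma_v| +
#'   \beta \frac{1}{\max(k_u, k_v)} \sum_{z \in \Gamma_u \cap \Gamma_v} k_z.}
#' With \eqn{\beta = 0} it reduces to the common-neighbours count.
#'
#' @inheritParams cn_score
#' @param params An [index_params()] object; uses `cn2d_beta`.
#' @return A single non-negative score.
#' @family similarity indices
#' @export
cn2d_score <- function(g, u, v, params = index_params()) {
  params <- as_index_params(params)
  z <- common_neighbor_names(g, u, v)
  if (length(z) == 0L) return(0)
  ku <- igraph::degree(g, as.character(u))
  kv <- igraph::degree(g, as.character(v))
  length(z) + params$cn2d_beta * sum(igraph::degree(g, z)) / max(ku, kv)
}

#' Local attribute closeness (LC)
#'
#' The local half of the LGC index: over the common neighbours \eqn{z} of
#' the pair,
#' \deqn{LC_{uv} = \sum_{z \in \Gamma_u \cap \Gamma_v}
#'   \frac{C_{u,v} + CC_z}{k_z},}
#' where \eqn{C_{u,v}} is the pair closeness ([pair_closeness()]) and
#' \eqn{CC_z} the local clustering coefficient of \eqn{z}. Zero when the
#' pair shares no neighbours.
#'
#' @inheritParams cn_score
#' @param stats Optional precomputed [graph_stats()] (unused here, accepted
#'   for a uniform scorer signature).
#' @return A single non-negative score.
#' @family similarity indices
#' @export
lc_score <- function(g, u, v, stats = NULL) {
  z <- common_neighbor_names(g, u, v)
  if (length(z) == 0L) return(0)
  cuv <- pair_closeness(g, u, v)
  sum((cuv + local_clustering(g, z)) / igraph::degree(g, z))
}

#' Global attribute closeness (GC)
#'
#' The global half of the LGC index, combining pair closeness with the
#' network averages: with the default product form
#' \eqn{GC_{uv} = C_{u,v} \cdot CC / d}, where \eqn{CC} is the average
#' clustering coefficient and \eqn{d} the average shortest path length of
#' the whole (training) graph. The inverse form \eqn{C_{u,v} / (d \cdot CC)}
#' is selected by `gc_form = "inverse"` and is undefined on triangle-free
#' networks.
#'
#' @inheritParams cn_score
#' @param stats Precomputed [graph_stats()] of `g`; computed if `NULL`.
#' @param params An [index_params()] object; uses `gc_form`.
#' @return A single non-negative score.
#' @family similarity indices
#' @export
gc_score <- function(g, u, v, stats = NULL, params = index_params()) {
  params <- as_index_params(params)
  if (is.null(stats)) stats <- graph_stats(g)
  if (stats$avg_shortest_path <= 0) {
    stop("global closeness needs a positive average shortest path length ",
         "(graph has no connected pair)", call. = FALSE)
  }
  cuv <- pair_closeness(g, u, v)
  gc_term(cuv, stats, params)
}

gc_term <- function(cuv, stats, params) {
  if (params$gc_form == "product") {
    cuv * stats$avg_clustering / stats$avg_shortest_path
  } else {
    if (stats$avg_clustering == 0) {
      stop("gc_form = \"inverse\" is undefined when the average clustering ",
           "coefficient is 0 (triangle-free network)", call. = FALSE)
    }
    cuv / (stats$avg_shortest_path * stats$avg_clustering)
  }
}

#' LGC index: weighted local and global closeness
#'
#' The headline index: a convex combination of the local term ([lc_score()])
#' and the global term ([gc_score()]),
#' \deqn{S_{uv} = \lambda \sum_{z \in \Gamma_u \cap \Gamma_v}
#'   \frac{C_{u,v} + CC_z}{k_z} + (1 - \lambda)\, \frac{C_{u,v}\, CC}{d}.}
#' \eqn{\lambda = 1} recovers LC, \eqn{\lambda = 0} recovers GC.
#'
#' @inheritParams gc_score
#' @param params An [index_params()] object; uses `lambda_weight` and
#'   `gc_form`.
#' @return A single non-negative score.
#' @family similarity indices
#' @export
lgc_score <- function(g, u, v, stats = NULL, params = index_params()) {
  params <- as_index_params(params)
  if (is.null(stats)) stats <- graph_stats(g)
  lam <- params$lambda_weight
  loc <- if (lam > 0) lc_score(g, u, v, stats) else 0
  glo <- if (lam < 1) gc_score(g, u, v, stats, params) else 0
  lam * loc + (1 - lam) * glo
}

#' LGC* index: LGC with a squared local numerator
#'
#' Identical to [lgc_score()] except the per-neighbour local numerator is
#' squared,
#' \deqn{S_{uv} = \lambda \sum_{z} \frac{(C_{u,v} + CC_z)^2}{k_z}
#'   + (1 - \lambda)\, GC_{uv},}
#' which widens the gap between high- and low-proximity pairs: values above
#' 1 are amplified, values below 1 shrink.
#'
#' @inheritParams lgc_score
#' @return A single non-negative score.
#' @family similarity indices
#' @export
lgc_star_score <- function(g, u, v, stats = NULL, params = index_params()) {
  params <- as_index_params(params)
  if (is.null(stats)) stats <- graph_stats(g)
  lam <- params$lambda_weight
  loc <- 0
  if (lam > 0) {
    z <- common_neighbor_names(g, u, v)
    if (length(z) > 0L) {
      cuv <- pair_closeness(g, u, v)
      loc <- sum((cuv + local_clustering(g, z))^2 / igraph::degree(g, z))
    }
  }
  glo <- if (lam < 1) gc_score(g, u, v, stats, params) else 0
  lam * loc + (1 - lam) * glo
}
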