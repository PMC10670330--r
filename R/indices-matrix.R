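# Dense-matrix path-counting indices. Both need O(n^2) memory and O(n^3)
# time, so they are gated by params$dense_cap.

dense_adjacency <- function(g, params, what) {
  n <- igraph::vcount(g)
  if (n > params$dense_cap) {
    stop(sprintf(paste0(
      "%s uses a dense %d x %d matrix; the graph exceeds dense_cap = %d. ",
      "Raise index_params(dense_cap = ...) if you accept the O(n^3) cost."),
      what, n, n, params$dense_cap), call. = FALSE)
  }
  igraph::as_adjacency_matrix(g, sparse = FALSE)
}

pairs_to_indices <- function(g, pairs) {
  nm <- igraph::V(g)$name
  ui <- match(pairs[, 1L], nm)
  vi <- match(pairs[, 2L], nm)
  if (anyNA(ui) || anyNA(vi)) {
    bad <- unique(c(pairs[, 1L][is.na(ui)], pairs[, 2L][is.na(vi)]))
    stop("unknown node(s) in pair set: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  cbind(ui, vi)
}

#' Katz index over a set of node pairs
#'
#' All-path similarity \eqn{S = (I - \beta A)^{-1} - I}, damping longer
#' paths geometrically. The series converges only for
#' \eqn{\beta < 1 / \rho(A)} (the reciprocal adjacency spectral radius);
#' the bound is validated before inverting and violations error with the
#' admissible range.
#'
#' @param g An undirected igraph graph with named vertices.
#' @param params An [index_params()] object; uses `katz_beta`, `dense_cap`.
#' @param pairs Two-column character matrix of node pairs to report;
#'   defaults to [candidate_pairs()] of `g`.
#' @return A `score_table` (see [score_index()]).
#' @family similarity indices
#' @export
katz_score <- function(g, params = index_params(), pairs = NULL) {
  check_graph(g); g <- ensure_names(g)
  params <- as_index_params(params)
  A <- dense_adjacency(g, params, "Katz")
  if (nrow(A) > 0L && params$katz_beta > 0) {
    rho <- max(abs(eigen(A, symmetric = TRUE, only.values = TRUE)$values))
    if (rho > 0 && params$katz_beta >= 1 / rho) {
      stop(sprintf(
        "katz_beta = %g is not below the spectral bound 1/rho(A) = %.6g",
        params$katz_beta, 1 / rho), call. = FALSE)
    }
  }
  S <- solve(diag(nrow(A)) - params$katz_beta * A) - diag(nrow(A))
  score_from_matrix(g, S, pairs, index = "katz", params = params)
}

#' Local-path index over a set of node pairs
#'
#' Counts 2-step walks plus lightly weighted 3-step walks between the pair:
#' \eqn{S = A^2 + \epsilon A^3}. With \eqn{\epsilon = 0} it reduces to the
#' common-neighbour count.
#'
#' @inheritParams katz_score
#' @return A `score_table` (see [score_index()]).
#' @family similarity indices
#' @export
lp_score <- function(g, params = index_params(), pairs = NULL) {
  check_graph(g); g <- ensure_names(g)
  params <- as_index_params(params)
  A <- dense_adjacency(g, params, "LP")
  A2 <- A %*% A
  S <- A2 + params$lp_epsilon * (A2 %*% A)
  score_from_matrix(g, S, pairs, index = "lp", params = params)
}

score_from_matrix <- function(g, S, pairs, index, params) {
  if (is.null(pairs)) pairs <- candidate_pairs(g)
  pairs <- canonical_pairs(pairs)
  idx <- pairs_to_indices(g, pairs)
  sc <- S[idx]
  new_score_table(pairs, sc, index = index, params = params)
}
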