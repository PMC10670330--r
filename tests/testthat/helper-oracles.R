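# Independent brute-force oracles. These deliberately avoid the package's
# own code paths: they work from the raw edge list with plain set
# operations and dense matrix arithmetic.

# edge list as a plain 2-column character matrix
raw_edges <- function(g) igraph::as_edgelist(g, names = TRUE)

# neighbour sets rebuilt by scanning the edge list
raw_neighbors <- function(el, v) {
  unique(c(el[el[, 1L] == v, 2L], el[el[, 2L] == v, 1L]))
}

raw_degree <- function(el, v) length(raw_neighbors(el, v))

raw_has_edge <- function(el, a, b) {
  any((el[, 1L] == a & el[, 2L] == b) | (el[, 1L] == b & el[, 2L] == a))
}

raw_clustering <- function(el, v) {
  nb <- raw_neighbors(el, v)
  k <- length(nb)
  if (k < 2L) return(0)
  links <- 0L
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      if (raw_has_edge(el, nb[i], nb[j])) links <- links + 1L
    }
  }
  2 * links / (k * (k - 1))
}

oracle_cn <- function(el, u, v) length(intersect(raw_neighbors(el, u),
                                                 raw_neighbors(el, v)))

oracle_aa <- function(el, u, v) {
  z <- intersect(raw_neighbors(el, u), raw_neighbors(el, v))
  if (length(z) == 0L) return(0)
  sum(vapply(z, function(w) 1 / log(raw_degree(el, w)), numeric(1L)))
}

oracle_ra <- function(el, u, v) {
  z <- intersect(raw_neighbors(el, u), raw_neighbors(el, v))
  if (length(z) == 0L) return(0)
  sum(vapply(z, function(w) 1 / raw_degree(el, w), numeric(1L)))
}

oracle_cclp <- function(el, u, v) {
  z <- intersect(raw_neighbors(el, u), raw_neighbors(el, v))
  if (length(z) == 0L) return(0)
  sum(vapply(z, function(w) raw_clustering(el, w), numeric(1L)))
}

# dense Floyd-Warshall all-pairs distances (Inf where unreachable)
oracle_floyd_warshall <- function(g) {
  n <- igraph::vcount(g)
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  D <- matrix(Inf, n, n)
  D[A > 0] <- 1
  diag(D) <- 0
  for (k in seq_len(n)) {
    D <- pmin(D, outer(D[, k], D[k, ], `+`))
  }
  dimnames(D) <- list(igraph::V(g)$name, igraph::V(g)$name)
  D
}

# truncated Katz power series sum_{l=1}^{L} beta^l A^l
oracle_katz_series <- function(g, beta, L = 20L) {
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  P <- diag(nrow(A))
  S <- matrix(0, nrow(A), ncol(A))
  for (l in seq_len(L)) {
    P <- P %*% A
    S <- S + beta^l * P
  }
  dimnames(S) <- list(igraph::V(g)$name, igraph::V(g)$name)
  S
}

# AUC as the normalised Mann-Whitney U statistic (midranks handle ties)
oracle_auc_mwu <- function(pos, neg) {
  r <- rank(c(pos, neg))
  n1 <- length(pos); n2 <- length(neg)
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

# a score table from explicit pairs and scores (pairs must be canonical)
fake_score_table <- function(u, v, score) {
  linkclose:::new_score_table(cbind(u, v), score, index = "manual",
                              params = NULL)
}

random_er <- function(n, p, seed) {
  generate_graph("erdos_renyi", n = n, p = p, seed = seed)
}

spectral_radius <- function(g) {
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  max(abs(eigen(A, symmetric = TRUE, only.values = TRUE)$values))
}

karate_graph <- function() {
  g <- igraph::make_graph("Zachary")
  igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
  g
}
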