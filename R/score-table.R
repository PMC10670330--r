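#' Candidate pairs for link prediction
#'
#' All unordered pairs of distinct nodes *not* joined by an edge — the
#' universe over which a link predictor is asked to rank. Pairs are returned
#' canonically (sorted within pair, pairs sorted lexicographically).
#'
#' @param g An undirected igraph graph with named vertices.
#' @return A two-column character matrix (columns `u`, `v`); zero rows for a
#'   complete graph.
#' @note Materialises an n x n logical matrix, so it is intended for the
#'   small-to-medium networks (up to a few thousand nodes) this package
#'   targets.
#' @export
candidate_pairs <- function(g) {
  check_graph(g); g <- ensure_names(g)
  n <- igraph::vcount(g)
  if (n == 0L) stop("candidate_pairs() requires a non-empty graph", call. = FALSE)
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE) > 0
  hit <- which(upper.tri(adj) & !adj, arr.ind = TRUE)
  nm <- igraph::V(g)$name
  pairs <- canonical_pairs(cbind(nm[hit[, 1L]], nm[hit[, 2L]]))
  pairs[order_pairs(pairs), , drop = FALSE]
}

new_score_table <- function(pairs, scores, index, params) {
  tab <- data.frame(u = pairs[, 1L], v = pairs[, 2L],
                    score = as.numeric(scores),
                    stringsAsFactors = FALSE)
  ord <- order(-tab$score, tab$u, tab$v, method = "radix")
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "index") <- index
  attr(tab, "params") <- params
  class(tab) <- c("score_table", "data.frame")
  tab
}

index_names <- c("cn", "aa", "ra", "pa", "katz", "lp",
                 "cn2d", "cclp", "lc", "gc", "lgc", "lgc_star")

#' Score a set of node pairs under one similarity index
#'
#' Uniform dispatch over the twelve indices. Network-level quantities
#' (degrees, clustering, closeness, averages) are computed once per call,
#' never per pair, and always on the graph passed in — during evaluation
#' that is the training graph, so no probe information leaks into scores.
#'
#' @param g An undirected igraph graph with named vertices.
#' @param index One of `"cn"`, `"aa"`, `"ra"`, `"pa"`, `"katz"`, `"lp"`,
#'   `"cn2d"`, `"cclp"`, `"lc"`, `"gc"`, `"lgc"`, `"lgc_star"`.
#' @param params An [index_params()] object.
#' @param pairs Two-column character matrix of node pairs to score;
#'   defaults to [candidate_pairs()] of `g`.
#' @return A `score_table`: a data frame with columns `u`, `v`, `score`,
#'   pairs canonical, rows sorted by descending score then canonical pair
#'   order. Symmetric by construction: the score is attached to the
#'   unordered pair.
#' @examples
#' g <- generate_graph("path", n = 3)
#' score_index(g, "cn")   # the two path ends share one neighbour
#' @export
score_index <- function(g, index, params = index_params(), pairs = NULL) {
  check_graph(g); g <- ensure_names(g)
  params <- as_index_params(params)
  if (length(index) != 1L || !index %in% index_names) {
    stop("unknown index '", paste(index, collapse = ","), "'; valid names: ",
         paste(index_names, collapse = ", "), call. = FALSE)
  }
  if (index == "katz") return(katz_score(g, params, pairs))
  if (index == "lp") return(lp_score(g, params, pairs))

  if (is.null(pairs)) pairs <- candidate_pairs(g)
  pairs <- canonical_pairs(pairs)
  idx <- pairs_to_indices(g, pairs)
  if (any(idx[, 1L] == idx[, 2L])) {
    stop("pairs of identical nodes cannot be scored", call. = FALSE)
  }

  n <- igraph::vcount(g)
  nbrs <- igraph::adjacent_vertices(g, igraph::V(g))
  nbrs <- lapply(nbrs, as.integer)
  deg <- unname(igraph::degree(g))

  need_cc <- index %in% c("cclp", "lc", "lgc", "lgc_star")
  need_clo <- index %in% c("lc", "gc", "lgc", "lgc_star")
  need_gc <- index %in% c("gc", "lgc", "lgc_star") && params$lambda_weight < 1
  need_gc <- need_gc || index == "gc"
  cc <- if (need_cc) unname(local_clustering(g)) else NULL
  clo <- if (need_clo) unname(closeness_centrality(g)) else NULL

  gcf <- NULL
  if (need_gc) {
    stats <- graph_stats(g)
    if (stats$avg_shortest_path <= 0) {
      stop("global closeness needs a positive average shortest path length ",
           "(graph has no connected pair)", call. = FALSE)
    }
    gcf <- if (params$gc_form == "product") {
      stats$avg_clustering / stats$avg_shortest_path
    } else {
      if (stats$avg_clustering == 0) {
        stop("gc_form = \"inverse\" is undefined when the average clustering ",
             "coefficient is 0 (triangle-free network)", call. = FALSE)
      }
      1 / (stats$avg_shortest_path * stats$avg_clustering)
    }
  }

  lam <- params$lambda_weight
  score_one <- switch(index,
    cn = function(ui, vi) {
      z <- nbrs[[ui]]; length(z[match(z, nbrs[[vi]], 0L) > 0L])
    },
    aa = function(ui, vi) {
      z <- nbrs[[ui]]; z <- z[match(z, nbrs[[vi]], 0L) > 0L]
      if (length(z) == 0L) 0 else sum(1 / log(deg[z]))
    },
    ra = function(ui, vi) {
      z <- nbrs[[ui]]; z <- z[match(z, nbrs[[vi]], 0L) > 0L]
      if (length(z) == 0L) 0 else sum(1 / deg[z])
    },
    pa = function(ui, vi) deg[ui] * deg[vi],
    cclp = function(ui, vi) {
      z <- nbrs[[ui]]; z <- z[match(z, nbrs[[vi]], 0L) > 0L]
      if (length(z) == 0L) 0 else sum(cc[z])
    },
    cn2d = function(ui, vi) {
      z <- nbrs[[ui]]; z <- z[match(z, nbrs[[vi]], 0L) > 0L]
      if (length(z) == 0L) return(0)
      length(z) + params$cn2d_beta * sum(deg[z]) / max(deg[ui], deg[vi])
    },
    lc = function(ui, vi) {
      z <- nbrs[[ui]]; z <- z[match(z, nbrs[[vi]], 0L) > 0L]
      if (length(z) == 0L) return(0)
      sum((clo[ui] + clo[vi] + cc[z]) / deg[z])
    },
    gc = function(ui, vi) (clo[ui] + clo[vi]) * gcf,
    lgc = function(ui, vi) {
      loc <- 0
      if (lam > 0) {
        z <- nbrs[[ui]]; z <- z[match(z, nbrs[[vi]], 0L) > 0L]
        if (length(z) > 0L) loc <- sum((clo[ui] + clo[vi] + cc[z]) / deg[z])
      }
      glo <- if (lam < 1) (clo[ui] + clo[vi]) * gcf else 0
      lam * loc + (1 - lam) * glo
    },
    lgc_star = function(ui, vi) {
      loc <- 0
      if (lam > 0) {
        z <- nbrs[[ui]]; z <- z[match(z, nbrs[[vi]], 0L) > 0L]
        if (length(z) > 0L) {
          loc <- sum((clo[ui] + clo[vi] + cc[z])^2 / deg[z])
        }
      }
      glo <- if (lam < 1) (clo[ui] + clo[vi]) * gcf else 0
      lam * loc + (1 - lam) * glo
    }
  )

  np <- nrow(pairs)
  sc <- if (np == 0L) numeric(0L) else {
    vapply(seq_len(np), function(k) score_one(idx[k, 1L], idx[k, 2L]),
           numeric(1L))
  }
  new_score_table(pairs, unname(sc), index = index, params = params)
}

#' @export
print.score_table <- function(x, n = 10L, ...) {
  idx <- attr(x, "index")
  cat(sprintf("Score table%s: %d pairs\n",
              if (!is.null(idx)) paste0(" (", idx, ")") else "", nrow(x)))
  print.data.frame(utils::head(x, n), row.names = FALSE)
  if (nrow(x) > n) cat(sprintf("... %d more pairs\n", nrow(x) - n))
  invisible(x)
}

#' Write a score table as tab-separated text
#'
#' Columns `node_u`, `node_v`, `score`; rows already sorted by descending
#' score then canonical pair order.
#'
#' @param tab A `score_table` from [score_index()].
#' @param sink Path or writable connection.
#' @return Invisibly, `tab`.
#' @export
write_score_table <- function(tab, sink) {
  out <- data.frame(node_u = tab$u, node_v = tab$v, score = tab$score)
  utils::write.table(out, sink, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}

# Named score vector keyed by canonical pair; pairs absent from the table
# score 0 so every index ranks the same universe.
score_lookup <- function(tab, pairs) {
  if (nrow(pairs) == 0L) return(numeric(0L))
  keys <- pair_keys(pairs)
  tabkeys <- paste(tab$u, tab$v, sep = "\r")
  sc <- tab$score[match(keys, tabkeys)]
  sc[is.na(sc)] <- 0
  sc
}
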