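# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so callers never perturb the global RNG
#' state. A `NULL` seed evaluates the expression under the current state.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Canonicalise a two-column character matrix of node pairs: sort within each
# pair (C-locale radix order) so (u, v) and (v, u) share one representation.
canonical_pairs <- function(pairs) {
  if (is.null(dim(pairs))) pairs <- matrix(pairs, ncol = 2L)
  u <- as.character(pairs[, 1L])
  v <- as.character(pairs[, 2L])
  swap <- rank_lt(v, u)
  tmp <- u[swap]
  u[swap] <- v[swap]
  v[swap] <- tmp
  cbind(u, v, deparse.level = 0L)
}

# TRUE where a < b in C-locale string order (vectorised: ranks against the
# radix-sorted pool of labels, locale-independent).
rank_lt <- function(a, b) {
  if (length(a) == 0L) return(logical(0L))
  lvl <- sort(unique(c(a, b)), method = "radix")
  match(a, lvl) < match(b, lvl)
}

# Single string key per unordered pair; input need not be canonical.
pair_keys <- function(pairs) {
  cp <- canonical_pairs(pairs)
  paste(cp[, 1L], cp[, 2L], sep = "\r")
}

# Order pairs lexicographically (first node, then second), C locale.
order_pairs <- function(pairs) {
  order(pairs[, 1L], pairs[, 2L], method = "radix")
}

# Validate that vertices exist; errors like a key lookup would.
check_vertex <- function(g, v, arg = "v") {
  nm <- igraph::V(g)$name
  bad <- setdiff(as.character(v), nm)
  if (length(bad) > 0L) {
    stop(sprintf("unknown node%s in `%s`: %s",
                 if (length(bad) > 1L) "s" else "", arg,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

check_graph <- function(g) {
  if (!igraph::is_igraph(g)) {
    stop("`g` must be an igraph graph (see read_edgelist(), generate_graph())",
         call. = FALSE)
  }
  if (igraph::is_directed(g)) stop("graph must be undirected", call. = FALSE)
  invisible(TRUE)
}

# All trial seeds drawn once under the master seed, so trials are independent
# draws yet the whole experiment is a pure function of the master seed.
trial_seeds <- function(master_seed, reps, streams = 2L) {
  with_seed(master_seed, matrix(
    sample.int(2147483646L, reps * streams, replace = FALSE),
    nrow = reps, ncol = streams
  ))
}

# Ensure every vertex has a character name; generators label 1..n.
ensure_names <- function(g) {
  if (is.null(igraph::V(g)$name)) {
    igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
  }
  g
}
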