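#' Read an undirected simple graph from a plain-text edge list
#'
#' Parses a whitespace-delimited edge list: one edge per line, the first two
#' tokens naming the endpoints (extra tokens, e.g. weights, are ignored).
#' Blank lines and lines starting with `#` are skipped. Duplicate edges —
#' including reversed duplicates — collapse to a single undirected edge.
#' Node identifiers are kept as opaque strings; no integer coding is assumed.
#'
#' @param source Path to a file, or a connection open for reading.
#' @return An undirected simple [igraph::igraph] graph with named vertices.
#' @details Self-loop lines (`a a`) are rejected: the graphs handled here are
#'   simple. A line with fewer than two tokens raises a parse error naming
#'   the offending line number.
#' @seealso [write_edgelist()]
#' @examples
#' f <- tempfile()
#' writeLines(c("# toy path", "a b", "b c", "b a"), f)
#' g <- read_edgelist(f)
#' igraph::ecount(g)  # 2: "b a" collapses into "a b"
#' @export
read_edgelist <- function(source) {
  lines <- readLines(source, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) {
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  toks <- strsplit(trimws(lines[idx]), "\\s+")
  nt <- lengths(toks)
  if (any(nt < 2L)) {
    bad <- idx[which(nt < 2L)[1L]]
    stop(sprintf("malformed edge list: line %d has fewer than 2 tokens", bad),
         call. = FALSE)
  }
  u <- vapply(toks, `[[`, character(1L), 1L)
  v <- vapply(toks, `[[`, character(1L), 2L)
  loop <- u == v
  if (any(loop)) {
    stop(sprintf("self-loop not allowed: line %d ('%s %s')",
                 idx[which(loop)[1L]], u[which(loop)[1L]], v[which(loop)[1L]]),
         call. = FALSE)
  }
  cp <- canonical_pairs(cbind(u, v))
  cp <- cp[!duplicated(paste(cp[, 1L], cp[, 2L], sep = "\r")), , drop = FALSE]
  igraph::graph_from_edgelist(cp, directed = FALSE)
}

#' Write a graph as a canonical plain-text edge list
#'
#' One edge per line, endpoints separated by a single space, each pair sorted
#' internally and pairs sorted lexicographically (C locale), so output is
#' deterministic and `read_edgelist(write_edgelist(g))` reproduces the edge
#' set exactly.
#'
#' @param g An undirected igraph graph.
#' @param sink Path or writable connection.
#' @return Invisibly, the character vector of lines written.
#' @note Isolated vertices cannot be expressed in edge-list format and are
#'   dropped on a round trip.
#' @seealso [read_edgelist()]
#' @export
write_edgelist <- function(g, sink) {
  check_graph(g)
  g <- ensure_names(g)
  el <- igraph::as_edgelist(g, names = TRUE)
  if (nrow(el) == 0L) {
    lines <- character(0L)
  } else {
    cp <- canonical_pairs(el)
    cp <- cp[order_pairs(cp), , drop = FALSE]
    lines <- paste(cp[, 1L], cp[, 2L])
  }
  writeLines(lines, sink)
  invisible(lines)
}
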