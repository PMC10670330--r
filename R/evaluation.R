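#' Random edge holdout split
#'
#' Partitions the edge set into a training part \eqn{E_T} and a probe part
#' \eqn{E_P} by sampling edges uniformly without replacement:
#' \eqn{E_T \cup E_P = E}, \eqn{E_T \cap E_P = \emptyset}. The training
#' graph keeps *all* nodes of the original graph, even ones isolated by the
#' removal — the split acts on edges only.
#'
#' @param g An undirected igraph graph with named vertices.
#' @param ratio Fraction of edges kept for training, in (0, 1); the training
#'   graph gets `round(ratio * m)` edges and the probe set the remainder.
#' @param seed Integer seed making the split reproducible.
#' @return An object of class `edge_split`: list with `train` (igraph graph),
#'   `probe` (two-column character matrix of held-out edges, canonical
#'   order), `ratio`, `seed`.
#' @examples
#' g <- generate_graph("erdos_renyi", n = 20, p = 0.3, seed = 1)
#' sp <- split_edges(g, ratio = 0.9, seed = 7)
#' nrow(sp$probe) + igraph::ecount(sp$train) == igraph::ecount(g)
#' @export
split_edges <- function(g, ratio, seed) {
  check_graph(g); g <- ensure_names(g)
  if (!is.numeric(ratio) || length(ratio) != 1L || ratio <= 0 || ratio >= 1) {
    stop("`ratio` must be a single number strictly between 0 and 1",
         call. = FALSE)
  }
  m <- igraph::ecount(g)
  if (m < 2L) stop("need at least 2 edges to split", call. = FALSE)
  n_train <- as.integer(round(ratio * m))
  n_probe <- m - n_train
  if (n_probe < 1L || n_train < 1L) {
    stop(sprintf(
      "ratio %g on %d edges leaves an empty %s set", ratio, m,
      if (n_probe < 1L) "probe" else "training"), call. = FALSE)
  }
  probe_ids <- with_seed(seed, sort(sample.int(m, n_probe)))
  el <- igraph::as_edgelist(g, names = TRUE)
  probe <- canonical_pairs(el[probe_ids, , drop = FALSE])
  probe <- probe[order_pairs(probe), , drop = FALSE]
  train <- igraph::delete_edges(g, probe_ids)
  structure(list(train = train, probe = probe,
                 ratio = ratio, seed = as.integer(seed)),
            class = "edge_split")
}

#' @export
print.edge_split <- function(x, ...) {
  cat(sprintf(
    "Edge split (ratio %.2f, seed %d): %d training edges, %d probe edges, %d nodes\n",
    x$ratio, x$seed, igraph::ecount(x$train), nrow(x$probe),
    igraph::vcount(x$train)))
  invisible(x)
}

#' AUC of a score table against probe and negative pairs
#'
#' The link-prediction AUC: the probability that a positive (probe) pair
#' outscores a negative (non-edge) pair, ties counted half. With `N1`
#' comparisons won by the positive, `N2` tied, and `N3` total, the value is
#' \eqn{(N_1 + 0.5 N_2) / N_3}. Pairs missing from the table score 0.
#'
#' @param scores A `score_table` from [score_index()].
#' @param probe_edges Two-column character matrix of positive pairs.
#' @param non_edges Two-column character matrix of negative pairs (non-edges
#'   of the *original* graph, i.e. pairs in neither the training nor the
#'   probe set).
#' @param mode `"auto"` (default) uses every positive-negative comparison
#'   when there are at most `exhaustive_limit` of them and sampling
#'   otherwise; `"exhaustive"` and `"sampled"` force one behaviour.
#' @param n_samples Number of independent (positive, negative) draws in
#'   sampled mode. Default 10000.
#' @param seed Integer seed for sampled mode (ignored otherwise).
#' @param exhaustive_limit Comparison-count threshold for `"auto"`.
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(scores, probe_edges, non_edges,
                      mode = c("auto", "exhaustive", "sampled"),
                      n_samples = 10000L, seed = NULL,
                      exhaustive_limit = 1e6) {
  mode <- match.arg(mode)
  if (is.null(dim(probe_edges))) probe_edges <- matrix(probe_edges, ncol = 2L)
  if (is.null(dim(non_edges))) non_edges <- matrix(non_edges, ncol = 2L)
  if (nrow(probe_edges) == 0L) stop("empty positive (probe) set", call. = FALSE)
  if (nrow(non_edges) == 0L) stop("empty negative set", call. = FALSE)
  pos <- score_lookup(scores, probe_edges)
  neg <- score_lookup(scores, non_edges)
  total <- as.numeric(length(pos)) * length(neg)
  if (mode == "auto") {
    mode <- if (total <= exhaustive_limit) "exhaustive" else "sampled"
  }
  if (mode == "exhaustive") {
    sneg <- sort(neg)
    n1 <- sum(findInterval(pos, sneg, left.open = TRUE))  # strictly below pos
    n_le <- sum(findInterval(pos, sneg))                  # <= pos
    n2 <- n_le - n1
    (n1 + 0.5 * n2) / total
  } else {
    draws <- with_seed(seed, {
      i <- sample.int(length(pos), n_samples, replace = TRUE)
      j <- sample.int(length(neg), n_samples, replace = TRUE)
      cbind(i, j)
    })
    p <- pos[draws[, 1L]]; q <- neg[draws[, 2L]]
    (sum(p > q) + 0.5 * sum(p == q)) / n_samples
  }
}

#' Precision at the top m ranked pairs
#'
#' Ranks the scored candidate pairs by descending score, breaking ties by
#' canonical pair order (so the ranking is deterministic even for
#' tie-heavy scorers like common neighbours on sparse graphs), and returns
#' the fraction of the first `m` pairs that are probe edges.
#'
#' @param scores A `score_table` over the candidate universe (all non-edges
#'   of the training graph).
#' @param probe_edges Two-column character matrix of held-out edges.
#' @param m Number of top pairs to inspect; must not exceed the number of
#'   scored pairs.
#' @return Precision in \[0, 1\].
#' @export
precision_at <- function(scores, probe_edges, m) {
  if (is.null(dim(probe_edges))) probe_edges <- matrix(probe_edges, ncol = 2L)
  m <- as.integer(m)
  if (m < 1L) stop("`m` must be at least 1", call. = FALSE)
  if (m > nrow(scores)) {
    stop(sprintf("m = %d exceeds the %d scored pairs", m, nrow(scores)),
         call. = FALSE)
  }
  # score tables are already sorted desc score / canonical pair order
  topkeys <- paste(scores$u[seq_len(m)], scores$v[seq_len(m)], sep = "\r")
  hits <- sum(topkeys %in% pair_keys(probe_edges))
  hits / m
}

#' Repeated edge-holdout evaluation of one index
#'
#' For each of `reps` trials: split the edges at `ratio` with a trial seed
#' drawn from the master seed, score the *training* graph's candidate pairs
#' under `index`, then measure AUC (against the original graph's non-edges)
#' and precision at `m`. The whole run is a pure function of
#' `(g, index, params, ratio, reps, m, seed)`.
#'
#' @param g An undirected igraph graph with named vertices.
#' @param index Index name, see [score_index()].
#' @param params An [index_params()] object.
#' @param ratio Training fraction in (0, 1). Default 0.9 (the conventional
#'   9:1 split).
#' @param reps Number of independent splits. Default 50.
#' @param m Top-list size for precision; the string `"probe"` uses each
#'   trial's probe-set size. Default 100.
#' @param auc_mode,n_samples Passed to [auc_score()].
#' @param seed Master seed; all trial seeds derive from it.
#' @return An object of class `eval_result`: list with `index`, `ratio`,
#'   `reps`, `m`, `params`, `seed`, per-trial vectors `auc` and `precision`,
#'   and their means `auc_mean`, `precision_mean`.
#' @examples
#' g <- generate_graph("barabasi_albert", n = 60, m_attach = 3, seed = 2)
#' run_experiment(g, "ra", ratio = 0.9, reps = 3, m = 20, seed = 11)
#' @export
run_experiment <- function(g, index, params = index_params(), ratio = 0.9,
                           reps = 50L, m = 100L,
                           auc_mode = c("auto", "exhaustive", "sampled"),
                           n_samples = 10000L, seed = 42L) {
  check_graph(g); g <- ensure_names(g)
  auc_mode <- match.arg(auc_mode)
  params <- as_index_params(params)
  reps <- as.integer(reps)
  if (reps < 1L) stop("`reps` must be at least 1", call. = FALSE)

  # negatives: non-edges of the ORIGINAL graph (in neither E_T nor E_P)
  negatives <- candidate_pairs(g)
  if (nrow(negatives) == 0L) {
    stop("graph is complete; no negative pairs to rank against", call. = FALSE)
  }
  seeds <- trial_seeds(seed, reps, streams = 2L)

  auc_v <- numeric(reps); prec_v <- numeric(reps)
  for (t in seq_len(reps)) {
    sp <- split_edges(g, ratio, seeds[t, 1L])
    tab <- score_index(sp$train, index, params)
    auc_v[t] <- auc_score(tab, sp$probe, negatives, mode = auc_mode,
                          n_samples = n_samples, seed = seeds[t, 2L])
    m_eff <- if (identical(m, "probe")) nrow(sp$probe) else as.integer(m)
    prec_v[t] <- precision_at(tab, sp$probe, m_eff)
  }
  structure(
    list(index = index, ratio = ratio, reps = reps, m = m, params = params,
         seed = as.integer(seed), auc = auc_v, precision = prec_v,
         auc_mean = mean(auc_v), precision_mean = mean(prec_v)),
    class = "eval_result"
  )
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf(
    "Link-prediction evaluation: index %s, ratio %.2f, %d reps (seed %d)\n  AUC  mean %.4f (sd %.4f)\n  Prec mean %.4f (sd %.4f) at m = %s\n",
    x$index, x$ratio, x$reps, x$seed,
    x$auc_mean, stats::sd(x$auc),
    x$precision_mean, stats::sd(x$precision), as.character(x$m)))
  invisible(x)
}

#' Convert an evaluation to per-trial and aggregate tables
#'
#' @param x An `eval_result`.
#' @param ... Unused.
#' @return Data frame with one row per trial plus columns identifying the
#'   configuration.
#' @export
as.data.frame.eval_result <- function(x, ...) {
  data.frame(index = x$index, ratio = x$ratio, trial = seq_len(x$reps),
             auc = x$auc, precision = x$precision)
}

#' Sweep the lambda weight of LGC or LGC*
#'
#' Runs [run_experiment()] once per lambda value with the *same* master
#' seed, so every lambda sees identical splits and differences are
#' attributable to lambda alone (a paired comparison).
#'
#' @inheritParams run_experiment
#' @param index `"lgc"` or `"lgc_star"`.
#' @param lambdas Numeric vector of weights in \[0, 1\].
#' @return Data frame with columns `lambda`, `auc_mean`, `precision_mean`.
#' @export
lambda_sweep <- function(g, index = c("lgc", "lgc_star"), lambdas,
                         params = index_params(), ratio = 0.9, reps = 50L,
                         m = 100L, auc_mode = "auto", n_samples = 10000L,
                         seed = 42L) {
  index <- match.arg(index)
  stopifnot(is.numeric(lambdas), all(lambdas >= 0 & lambdas <= 1))
  rows <- lapply(lambdas, function(lam) {
    p <- params; p$lambda_weight <- lam
    r <- run_experiment(g, index, p, ratio = ratio, reps = reps, m = m,
                        auc_mode = auc_mode, n_samples = n_samples,
                        seed = seed)
    data.frame(lambda = lam, auc_mean = r$auc_mean,
               precision_mean = r$precision_mean)
  })
  do.call(rbind, rows)
}

#' Sweep the training ratio
#'
#' One aggregated row per training fraction; the default grid
#' `c(0.5, 0.6, 0.7, 0.8, 0.9)` probes robustness to sparser training data.
#'
#' @inheritParams run_experiment
#' @param ratios Numeric vector of training fractions in (0, 1).
#' @return Data frame with columns `ratio`, `auc_mean`, `precision_mean`.
#' @export
ratio_sweep <- function(g, index, params = index_params(),
                        ratios = c(0.5, 0.6, 0.7, 0.8, 0.9), reps = 50L,
                        m = 100L, auc_mode = "auto", n_samples = 10000L,
                        seed = 42L) {
  stopifnot(is.numeric(ratios), all(ratios > 0 & ratios < 1))
  rows <- lapply(ratios, function(r) {
    res <- run_experiment(g, index, params, ratio = r, reps = reps, m = m,
                          auc_mode = auc_mode, n_samples = n_samples,
                          seed = seed)
    data.frame(ratio = r, auc_mean = res$auc_mean,
               precision_mean = res$precision_mean)
  })
  do.call(rbind, rows)
}
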