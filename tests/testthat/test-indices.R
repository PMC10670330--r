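k4 <- generate_graph("complete", n = 4)
p3 <- fixture_figure1("a")
star <- generate_graph("star", n = 4)

test_that("neighbourhood indices match hand-evaluated fixtures", {
  expect_equal(cn_score(p3, "a", "c"), 1L)
  expect_equal(cn_score(k4, "1", "2"), 2L)
  expect_equal(aa_score(k4, "1", "2"), 2 / log(3))
  expect_equal(aa_score(p3, "a", "c"), 1 / log(2))
  expect_equal(ra_score(k4, "1", "2"), 2 / 3)
  expect_equal(ra_score(p3, "a", "c"), 0.5)
  expect_equal(pa_score(k4, "1", "2"), 9)
  expect_equal(pa_score(star, "2", "3"), 1)
  expect_equal(cclp_score(k4, "1", "2"), 2)
  expect_equal(cclp_score(p3, "a", "c"), 0)
  expect_equal(cn2d_score(k4, "1", "2"), 2 + 0.1 * (1 / 3) * 6)
  # no common neighbours => 0 for the whole family
  tt <- generate_graph("two_triangles")
  for (f in list(cn_score, aa_score, ra_score, cclp_score)) {
    expect_equal(unname(f(tt, "1", "4")), 0)
  }
  expect_error(cn_score(p3, "a", "zz"), "unknown node")
  expect_error(aa_score(p3, "a", "a"), "distinct")
})

test_that("CN/AA/RA/CCLP agree with naive edge-scan oracles on random graphs", {
  for (seed in 1:4) {
    g <- random_er(20, 0.2, seed = seed)
    el <- raw_edges(g)
    pairs <- candidate_pairs(g)
    take <- withr::with_seed(seed, sample(nrow(pairs), min(25L, nrow(pairs))))
    for (k in take) {
      u <- pairs[k, 1L]; v <- pairs[k, 2L]
      expect_equal(cn_score(g, u, v), oracle_cn(el, u, v))
      expect_equal(aa_score(g, u, v), oracle_aa(el, u, v))
      expect_equal(ra_score(g, u, v), oracle_ra(el, u, v))
      expect_equal(cclp_score(g, u, v), oracle_cclp(el, u, v))
    }
  }
})

test_that("LC, GC, LGC and LGC* match hand evaluations", {
  s4 <- graph_stats(k4)
  expect_equal(lc_score(k4, "1", "2"), 2)
  expect_equal(gc_score(k4, "1", "2", s4), 2)
  for (lam in c(0, 0.3, 0.8, 1)) {
    expect_equal(
      lgc_score(k4, "1", "2", s4, index_params(lambda_weight = lam)), 2)
  }
  expect_equal(lgc_star_score(k4, "1", "2", s4), 5.2)  # 0.8*2*(9/3) + 0.2*2
  # product and inverse forms coincide on K4 (CC = d = 1)
  expect_equal(
    gc_score(k4, "1", "2", s4, index_params(gc_form = "inverse")), 2)

  s3 <- graph_stats(p3)
  expect_equal(lc_score(p3, "a", "c"), 2 / 3)        # (4/3 + 0) / 2
  expect_equal(gc_score(p3, "a", "c", s3), 0)        # CC = 0, product form
  expect_equal(lgc_score(p3, "a", "c", s3), 0.8 * 2 / 3)
  expect_error(
    gc_score(p3, "a", "c", s3, index_params(gc_form = "inverse")),
    "clustering")

  ss <- graph_stats(star)
  expect_equal(lc_score(star, "2", "3"), 0.4)        # (1.2 + 0) / 3
})

test_that("endpoint reductions hold on random graphs", {
  for (seed in 1:10) {
    g <- random_er(18, 0.25, seed = seed)
    if (igraph::ecount(g) < 2) next
    pairs <- candidate_pairs(g)
    lam1 <- score_index(g, "lgc", index_params(lambda_weight = 1), pairs)
    lc <- score_index(g, "lc", pairs = pairs)
    expect_equal(lam1$score, lc$score)
    expect_identical(lam1[c("u", "v")], lc[c("u", "v")])

    lam0 <- score_index(g, "lgc", index_params(lambda_weight = 0), pairs)
    gc <- score_index(g, "gc", pairs = pairs)
    expect_equal(lam0$score, gc$score)

    star0 <- score_index(g, "lgc_star", index_params(lambda_weight = 0), pairs)
    expect_equal(star0$score, gc$score)

    cn2d0 <- score_index(g, "cn2d", index_params(cn2d_beta = 0), pairs)
    cn <- score_index(g, "cn", pairs = pairs)
    expect_equal(cn2d0$score, cn$score)

    lp0 <- score_index(g, "lp", index_params(lp_epsilon = 0), pairs)
    expect_equal(lp0$score, cn$score)  # 2-walks between non-adjacent = CN
  }
})

test_that("Katz matches the truncated power series and validates beta", {
  for (seed in 1:5) {
    g <- random_er(25, 0.15, seed = seed)
    rho <- spectral_radius(g)
    beta <- 0.1 / rho
    S <- oracle_katz_series(g, beta, L = 20L)
    tab <- katz_score(g, index_params(katz_beta = beta))
    ref <- S[cbind(tab$u, tab$v)]
    expect_lt(max(abs(tab$score - ref)), 1e-9)
  }
  g <- random_er(25, 0.15, seed = 1)
  rho <- spectral_radius(g)
  expect_error(katz_score(g, index_params(katz_beta = 1.01 / rho)),
               "spectral")
  tab0 <- katz_score(g, index_params(katz_beta = 0))
  expect_true(all(tab0$score == 0))
})

test_that("LP counts 2-walks plus weighted 3-walks", {
  # path a-b-c: one 2-walk a->b->c, no 3-walks
  tab <- lp_score(p3, index_params(lp_epsilon = 0.001))
  expect_equal(tab$score[tab$u == "a" & tab$v == "c"], 1)
  # adjacent K4 pair: 2 two-walks, 7 three-walks (A^3 = 7J - I off-diagonal)
  pr <- rbind(c("1", "2"))
  tab2 <- lp_score(k4, index_params(lp_epsilon = 0.001), pairs = pr)
  expect_equal(tab2$score, 2 + 0.001 * 7)
  # and the full matrix-walk oracle on a random graph
  g <- random_er(12, 0.3, seed = 2)
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  W <- A %*% A + 0.001 * (A %*% A %*% A)
  dimnames(W) <- list(igraph::V(g)$name, igraph::V(g)$name)
  tab3 <- lp_score(g, index_params(lp_epsilon = 0.001))
  expect_equal(tab3$score, unname(W[cbind(tab3$u, tab3$v)]))
})

test_that("score_index dispatch agrees with the per-pair scorers", {
  g <- random_er(15, 0.3, seed = 7)
  s <- graph_stats(g)
  pairs <- candidate_pairs(g)
  per_pair <- list(
    cn = function(u, v) cn_score(g, u, v),
    aa = function(u, v) aa_score(g, u, v),
    ra = function(u, v) ra_score(g, u, v),
    pa = function(u, v) pa_score(g, u, v),
    cclp = function(u, v) cclp_score(g, u, v),
    cn2d = function(u, v) cn2d_score(g, u, v),
    lc = function(u, v) lc_score(g, u, v, s),
    gc = function(u, v) gc_score(g, u, v, s),
    lgc = function(u, v) lgc_score(g, u, v, s),
    lgc_star = function(u, v) lgc_star_score(g, u, v, s)
  )
  for (nm in names(per_pair)) {
    tab <- score_index(g, nm, pairs = pairs)
    ref <- mapply(per_pair[[nm]], tab$u, tab$v)
    expect_equal(tab$score, unname(ref), tolerance = 1e-12,
                 label = paste("index", nm))
  }
  expect_error(score_index(g, "nope"), "valid names")
})

test_that("scores are symmetric, finite, non-negative and label-invariant", {
  g <- random_er(16, 0.25, seed = 11)
  pairs <- candidate_pairs(g)
  rev_pairs <- pairs[, c(2L, 1L)]
  for (nm in c("cn", "aa", "ra", "pa", "katz", "lp", "cn2d", "cclp",
               "lc", "gc", "lgc", "lgc_star")) {
    tab <- score_index(g, nm, pairs = pairs)
    expect_true(all(is.finite(tab$score)), label = paste(nm, "finite"))
    expect_true(all(tab$score >= 0), label = paste(nm, "non-negative"))
    # reversed input pairs canonicalise to the same keyed scores
    tab_rev <- score_index(g, nm, pairs = rev_pairs)
    expect_equal(linkclose:::score_lookup(tab_rev, pairs),
                 linkclose:::score_lookup(tab, pairs),
                 label = paste(nm, "symmetric"))
  }
  # relabeling invariance: permute names, scores follow the relabeled pairs
  perm <- withr::with_seed(5, sample(igraph::V(g)$name))
  g2 <- g
  igraph::V(g2)$name <- perm
  names(perm) <- igraph::V(g)$name   # old -> new mapping
  for (nm in c("cn", "ra", "katz", "lgc", "lgc_star")) {
    tab <- score_index(g, nm, pairs = pairs)
    mapped <- cbind(unname(perm[tab$u]), unname(perm[tab$v]))
    tab2 <- score_index(g2, nm, pairs = mapped)
    expect_equal(linkclose:::score_lookup(tab2, mapped), tab$score,
                 label = paste(nm, "relabel"))
  }
})

test_that("candidate pairs are exactly the non-adjacent distinct pairs", {
  expect_equal(nrow(candidate_pairs(k4)), 0L)
  cp <- candidate_pairs(p3)
  expect_equal(cp, cbind(u = "a", v = "c"), ignore_attr = TRUE)
  # empty graph on n nodes: all n(n-1)/2 pairs
  g <- igraph::make_empty_graph(0, directed = FALSE)
  g <- igraph::add_vertices(g, 6, name = letters[1:6])
  expect_equal(nrow(candidate_pairs(g)), 15L)
})
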