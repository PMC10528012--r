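he <- example_hypergraph()

test_that("HVC reproduces the hand-computed worked example", {
  t <- hvc_scores(he)
  s <- stats::setNames(t$score, t$node)
  expect_equal(unname(s["v2"]), 0.386921, tolerance = 1e-5)
  expect_equal(unname(s["v5"]), 0.338054, tolerance = 1e-5)
  expect_equal(unname(s["v1"]), 0.195465, tolerance = 1e-5)
  expect_equal(rank_nodes(t),
               c("v2", "v3", "v5", "v6", "v7", "v4", "v1", "v8",
                 "v9", "v10", "v11"))
})

test_that("HVC degenerates gracefully", {
  # highest order alone: L3 is a single edge, entropy 0 before and after
  t3 <- hvc_scores(he, orders = 3)
  expect_equal(t3$score, rep(0, 11))
  # pairwise-disjoint hyperedges: every line graph edgeless
  hd <- hypergraph(list(c("a", "b"), c("c", "d")))
  expect_equal(hvc_scores(hd)$score, rep(0, 4))
  expect_error(hvc_scores(he, orders = 0), ">= 1")
})

test_that("HVC equals the naive loop-and-eigen reference implementation", {
  set.seed(409)
  for (rep in 1:12) {
    h <- rand_test_hypergraph(sample(8:25, 1), sample(3:10, 1))
    got <- hvc_scores(h)
    ref <- oracle_hvc(h)
    expect_lt(max(abs(stats::setNames(got$score, got$node)[names(ref)] - ref)),
              1e-9)
  }
})

test_that("semi-SAVC truncates the order set and uses quadratic entropy", {
  # smax = 3 -> floor(3/2) = 1 -> orders {1}, quadratic backend
  t <- semi_savc_scores(he)
  ref <- hvc_scores(he, orders = 1, entropy = "quadratic")
  expect_equal(t$score, ref$score, tolerance = 1e-12)
  # frozen worked-example value (vertex removal shrinks the line graph)
  expect_equal(t$score[t$node == "v2"], 0.2561083, tolerance = 1e-6)
  # both modes agree when floor(smax/2) == 1
  expect_equal(semi_savc_scores(he, mode = "single")$score, t$score)
  # smax = 1: same order set as HVC, only the backend differs
  h1 <- hypergraph(list(c("a", "b"), c("b", "c")))
  expect_equal(semi_savc_scores(h1)$score,
               hvc_scores(h1, orders = 1, entropy = "quadratic")$score)
  # cumulative vs single differ once floor(smax/2) >= 2
  hp <- planted_overlap_hypergraph(30, 6, 8, 5, seed = 2)
  tc <- semi_savc_scores(hp, mode = "cumulative")
  ts <- semi_savc_scores(hp, mode = "single")
  expect_equal(tc$score,
               hvc_scores(hp, orders = 1:2, entropy = "quadratic")$score)
  expect_equal(ts$score,
               hvc_scores(hp, orders = 2, entropy = "quadratic")$score)
  expect_false(isTRUE(all.equal(tc$score, ts$score)))
})

test_that("HDC counts incident hyperedges and conserves cardinality mass", {
  t <- hdc_scores(he)
  s <- stats::setNames(t$score, t$node)
  expect_equal(unname(s["v4"]), 2)
  expect_equal(unname(s["v1"]), 1)
  expect_equal(sum(t$score), sum(hyperedge_sizes(he)))  # = 17
  expect_equal(hdc_scores(hypergraph(list(letters[1:4])))$score, rep(1, 4))
})

test_that("closeness uses 2-section BFS distances with component scaling", {
  t <- cc_scores(he)
  s <- stats::setNames(t$score, t$node)
  expect_equal(unname(s["v2"]), 10 / 14, tolerance = 1e-12)
  expect_equal(unname(s["v1"]), 10 / 22, tolerance = 1e-12)
  # complete 2-section: every score 1
  tk <- cc_scores(hypergraph(list(letters[1:5])))
  expect_equal(tk$score, rep(1, 5))
  # disconnected: Wasserman-Faust scaling keeps scores comparable
  hd <- hypergraph(list(c("a", "b", "c"), c("x", "y")))
  td <- cc_scores(hd)
  sd_ <- stats::setNames(td$score, td$node)
  expect_equal(unname(sd_["a"]), (2/4) * (2/2), tolerance = 1e-12)
  expect_equal(unname(sd_["x"]), (1/4) * (1/1), tolerance = 1e-12)
  expect_true(all(td$score > 0 & td$score <= 1))
})

test_that("vector centrality matches the analytic star Perron vector", {
  t <- vc_scores(he)
  s <- stats::setNames(t$score, t$node)
  expect_equal(unname(s["v2"]), (1/3) * (1/sqrt(6)) + (1/6) * (sqrt(3)/sqrt(6)),
               tolerance = 1e-9)
  expect_equal(unname(s["v2"]), 0.253934, tolerance = 1e-6)
  expect_equal(unname(s["v4"]), 0.219913, tolerance = 1e-6)
  expect_true(all(t$score >= 0))
  # edgeless 1-line graph -> all zeros
  hz <- hypergraph(list(c("a", "b"), c("c", "d")))
  expect_equal(vc_scores(hz)$score, rep(0, 4))
})

test_that("vector centrality ranks are normalisation-invariant and agree with igraph", {
  set.seed(410)
  for (rep in 1:6) {
    h <- rand_test_hypergraph(sample(10:25, 1), sample(4:10, 1))
    t2 <- vc_scores(h, normalization = "l2")
    tm <- vc_scores(h, normalization = "max")
    expect_equal(t2$rank, tm$rank)
    # cross-check the Perron vector against igraph eigenvector centrality
    l1 <- s_line_graph(h, 1)
    if (igraph::ecount(l1) == 0) next
    ig <- igraph::eigen_centrality(l1)$vector
    own <- hypervne:::perron_vector(hypervne:::line_graph_adjacency(h, 1))
    if (max(own) > 0) own <- own / max(own)
    # compare on the dominant component (igraph zeros elsewhere too)
    expect_equal(unname(own), unname(ig[names(own)]), tolerance = 1e-6)
  }
})

test_that("SHC equals the diagonal of the matrix exponential", {
  pair <- hypergraph(list(c("a", "b")))
  expect_equal(shc_scores(pair)$score, rep(cosh(1), 2), tolerance = 1e-10)
  # edgeless adjacency -> exp(0) = 1 each... a hypergraph always covers its
  # nodes, so use singleton hyperedges (no 2-section edges)
  hz <- hypergraph(list("a", "b", "c"))
  expect_equal(shc_scores(hz)$score, rep(1, 3), tolerance = 1e-12)
  set.seed(411)
  for (rep in 1:10) {
    h <- rand_test_hypergraph(sample(5:20, 1), sample(2:8, 1))
    got <- shc_scores(h)$score
    ref <- diag(as.matrix(Matrix::expm(adjacency_matrix(h))))
    expect_lt(max(abs(got - ref) / pmax(1, abs(ref))), 1e-8)
  }
})

test_that("every method scores every node and ranks deterministically", {
  methods <- list(hvc_scores, semi_savc_scores, hdc_scores, cc_scores,
                  vc_scores, shc_scores)
  for (f in methods) {
    t <- f(he)
    expect_equal(nrow(t), 11L)
    expect_true(all(is.finite(t$score)))
    expect_setequal(t$node, he$nodes)
    expect_equal(sort(t$rank), 1:11)
  }
})

test_that("rank_nodes breaks ties by first-appearance order", {
  t <- hdc_scores(he)
  r <- rank_nodes(t)
  expect_equal(r[1:6], c("v2", "v3", "v4", "v5", "v6", "v7"))  # all degree 2
  # all-equal scores keep input order
  ha <- hypergraph(list(c("z", "q", "a")))
  expect_equal(rank_nodes(hdc_scores(ha)), c("z", "q", "a"))
  # explicit two-node ordering
  hb <- hypergraph(list(c("a"), c("b"), c("b")))
  expect_equal(rank_nodes(hdc_scores(hb)), c("b", "a"))
})
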