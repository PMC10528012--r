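he <- example_hypergraph()

test_that("monotonicity hits its endpoints and the worked-example value", {
  expect_equal(monotonicity(c(5, 4, 3, 2, 1)), 1)
  expect_equal(monotonicity(rep(2.5, 6)), 0)
  expect_equal(monotonicity(hdc_scores(he)), (60 / 110)^2, tolerance = 1e-12)
  expect_error(monotonicity(3), "at least 2")
  # invariant under strictly monotone transforms of the scores
  set.seed(415)
  x <- sample(1:5, 20, replace = TRUE)
  expect_equal(monotonicity(x), monotonicity(exp(2 * x)))
  expect_equal(monotonicity(x), monotonicity(rank(x, ties.method = "min")))
  expect_true(monotonicity(x) >= 0 && monotonicity(x) <= 1)
})

test_that("tie detection rounds scores before grouping", {
  x <- c(1, 1 + 1e-14, 2)            # equal after rounding to 10 decimals
  expect_equal(monotonicity(x), monotonicity(c(1, 1, 2)))
  expect_equal(monotonicity(x, digits = 15), 1)
})

test_that("pearson matrix is symmetric with unit diagonal", {
  tabs <- list(HVC = hvc_scores(he), `semi-SAVC` = semi_savc_scores(he),
               HDC = hdc_scores(he), CC = cc_scores(he),
               VC = vc_scores(he), SHC = shc_scores(he))
  m <- pearson_matrix(tabs)
  expect_equal(dim(m), c(6L, 6L))
  expect_true(isSymmetric(m))
  expect_equal(unname(diag(m)), rep(1, 6))
  expect_true(all(m >= -1 - 1e-12 & m <= 1 + 1e-12))
  # a table against itself and against its negation
  t1 <- hvc_scores(he)
  t2 <- t1; t2$score <- -t2$score
  m2 <- pearson_matrix(list(a = t1, b = t1, c = t2))
  expect_equal(m2["a", "b"], 1, tolerance = 1e-12)
  expect_equal(m2["a", "c"], -1, tolerance = 1e-12)
})

test_that("pearson entry matches a textbook covariance computation", {
  a <- hvc_scores(he)
  b <- semi_savc_scores(he)
  m <- pearson_matrix(list(HVC = a, `semi-SAVC` = b))
  x <- a$score
  y <- b$score[match(a$node, b$node)]
  ref <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(m["HVC", "semi-SAVC"], ref, tolerance = 1e-12)
})

test_that("degenerate zero-variance scores are flagged as NA", {
  flat <- hdc_scores(hypergraph(list(letters[1:4])))   # all scores 1
  expect_warning(m <- pearson_matrix(list(flat = flat, hvc = hvc_scores(
    hypergraph(list(letters[1:4]))))), "zero-variance")
  expect_true(is.na(m["flat", "hvc"]))
  # misaligned node sets are an error
  other <- hdc_scores(hypergraph(list(c("x", "y"))))
  expect_error(pearson_matrix(list(a = hdc_scores(he), b = other)),
               "not aligned")
})

test_that("robustness curve matches an independent BFS oracle", {
  # removing the top 2 HVC nodes {v2, v3} (~20%) from the worked example
  removed <- rank_nodes(hvc_scores(he))[1:2]
  expect_equal(removed, c("v2", "v3"))
  got <- hypervne:::residual_lcc(he, removed)
  # oracle: brute-force residual 2-section + BFS component sizes
  res_edges <- lapply(he$hyperedges, setdiff, y = removed)
  res_edges <- res_edges[lengths(res_edges) > 0]
  pairs <- do.call(rbind, lapply(res_edges, function(e) {
    if (length(e) < 2) return(NULL)
    t(utils::combn(e, 2))
  }))
  pairs <- unique(t(apply(pairs, 1, sort)))
  keep <- setdiff(he$nodes, removed)
  sizes <- oracle_component_sizes(keep, pairs)
  expect_equal(got, max(sizes))
  expect_equal(got, 8L)   # {v4..v11} bridge through v4; v1 isolated
})

test_that("robustness LCC is non-increasing in the removal fraction", {
  ranking <- rank_nodes(hvc_scores(he))
  rc <- robustness_curve(he, ranking, fractions = c(0.1, 0.2, 0.3))
  expect_equal(rc$removed, c(2L, 3L, 4L))     # ceil(f * 11)
  expect_true(all(diff(rc$lcc) <= 0))
  expect_true(all(rc$lcc <= 11 - rc$removed))
  # removing everything leaves nothing
  expect_equal(hypervne:::residual_lcc(he, he$nodes), 0L)
  # removing nothing returns the original LCC
  expect_equal(hypervne:::residual_lcc(he, character(0)),
               max(igraph::components(two_section_graph(he))$csize))
  set.seed(416)
  h <- random_hypergraph(60, 30, size_mean = 5, seed = 23)
  rc2 <- robustness_curve(h, rank_nodes(hdc_scores(h)))
  expect_true(all(diff(rc2$lcc) <= 0))
})

test_that("saturation sweep at the full grid reproduces plain HVC seeds", {
  h <- planted_overlap_hypergraph(40, 8, 10, 6, seed = 31)
  smax <- max_overlap(h)
  expect_equal(smax, 6L)
  sw <- saturation_sweep(h, max_orders = smax, alpha = 0, kappa = 1.25,
                         gamma = 0.2, steps = 2, n_runs = 3, seed = 12)
  expect_equal(attr(sw, "seeds")[[as.character(smax)]],
               top_fraction_nodes(hvc_scores(h), 0.01))
  # alpha = 0: influence is exactly |seeds|/N whatever the order
  expect_equal(sw$influence, length(attr(sw, "seeds")[[1]]) / n_nodes(h))
  expect_error(saturation_sweep(h, max_orders = 99), "1..max_overlap")
  # rankings per grid entry are deterministic given the entropy backend
  s1 <- saturation_sweep(h, c(1, 3), alpha = 0, kappa = 1, gamma = 0,
                         steps = 1, n_runs = 2, seed = 1)
  s2 <- saturation_sweep(h, c(1, 3), alpha = 0, kappa = 1, gamma = 0,
                         steps = 1, n_runs = 2, seed = 1)
  expect_identical(attr(s1, "seeds"), attr(s2, "seeds"))
})
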