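# Independent reference implementations used as oracles.  These deliberately
# avoid the package's code paths (no incidence crossprod, no igraph): line
# graphs are built by explicit pair loops, entropies from hand-built
# Laplacians, components by a plain BFS.

# unique unordered 2-section pairs by brute-force enumeration
oracle_two_section_pairs <- function(h) {
  pairs <- character(0)
  for (e in h$hyperedges) {
    if (length(e) < 2L) next
    for (a in seq_len(length(e) - 1L))
      for (b in (a + 1L):length(e)) {
        key <- paste(sort(c(e[a], e[b])), collapse = "|")
        pairs <- c(pairs, key)
      }
  }
  unique(pairs)
}

# line-graph adjacency by pairwise set intersection loops
oracle_line_adj <- function(h, s) {
  M <- length(h$hyperedges)
  A <- matrix(0, M, M)
  if (M >= 2L) for (i in seq_len(M - 1L)) for (j in (i + 1L):M) {
    if (length(intersect(h$hyperedges[[i]], h$hyperedges[[j]])) >= s)
      A[i, j] <- A[j, i] <- 1
  }
  A
}

oracle_vn_entropy <- function(A) {
  d <- rowSums(A)
  m <- sum(d) / 2
  if (m == 0) return(0)
  L <- diag(d, nrow = nrow(A)) - A
  lam <- eigen(L / (2 * m), symmetric = TRUE, only.values = TRUE)$values
  lam <- lam[lam > 1e-14]
  -sum(lam * log(lam))
}

# naive HVC: rebuild every line graph, recompute every entropy by dense
# eigendecomposition, map and fuse with explicit loops
oracle_hvc <- function(h) {
  M <- length(h$hyperedges)
  N <- length(h$nodes)
  smax <- 0L
  if (M >= 2L) for (i in seq_len(M - 1L)) for (j in (i + 1L):M)
    smax <- max(smax, length(intersect(h$hyperedges[[i]], h$hyperedges[[j]])))
  score <- stats::setNames(numeric(N), h$nodes)
  if (smax == 0L) return(score)
  rj <- lengths(h$hyperedges)
  for (s in seq_len(smax)) {
    A <- oracle_line_adj(h, s)
    S0 <- oracle_vn_entropy(A)
    delta <- numeric(M)
    for (j in seq_len(M))
      delta[j] <- S0 - oracle_vn_entropy(A[-j, -j, drop = FALSE])
    for (i in seq_len(N)) {
      phi <- 0
      for (j in seq_len(M))
        if (h$nodes[i] %in% h$hyperedges[[j]]) phi <- phi + delta[j] / rj[j]
      score[i] <- score[i] + phi / s
    }
  }
  score
}

# plain BFS component sizes over an edge list given as two-column matrix
oracle_component_sizes <- function(nodes, pairs) {
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  if (length(pairs)) for (k in seq_len(nrow(pairs))) {
    a <- pairs[k, 1L]; b <- pairs[k, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  unvisited <- nodes
  sizes <- integer(0)
  while (length(unvisited)) {
    queue <- unvisited[1L]
    comp <- character(0)
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      if (!v %in% unvisited) next
      unvisited <- setdiff(unvisited, v)
      comp <- c(comp, v)
      queue <- c(queue, intersect(adj[[v]], unvisited))
    }
    sizes <- c(sizes, length(comp))
  }
  sizes
}

# independent SIR simulator: per-node loops over precomputed membership
# lists, probabilities from first principles (sum over incident hyperedges
# of alpha * eta^kappa, clamped)
oracle_sir_prevalence <- function(h, seeds, alpha, kappa, gamma, steps) {
  incident <- lapply(h$nodes, function(v)
    which(vapply(h$hyperedges, function(e) v %in% e, logical(1))))
  names(incident) <- h$nodes
  state <- stats::setNames(rep("S", length(h$nodes)), h$nodes)
  state[seeds] <- "I"
  for (t in seq_len(steps)) {
    infected_now <- names(state)[state == "I"]
    eta <- vapply(h$hyperedges, function(e) sum(e %in% infected_now),
                  numeric(1))
    to_infect <- character(0)
    for (v in names(state)[state == "S"]) {
      ev <- eta[incident[[v]]]
      ev <- ev[ev > 0]
      p <- min(1, sum(alpha * ev^kappa))
      if (stats::runif(1) < p) to_infect <- c(to_infect, v)
    }
    to_recover <- infected_now[stats::runif(length(infected_now)) < gamma]
    state[to_infect] <- "I"
    state[to_recover] <- "R"
  }
  mean(state != "S")
}

# small random hypergraph for property loops (independent of the package
# generator so generator bugs cannot mask core bugs)
rand_test_hypergraph <- function(n_nodes, n_edges) {
  nodes <- paste0("x", seq_len(n_nodes))
  edges <- lapply(seq_len(n_edges), function(j) {
    r <- sample(1:min(6L, n_nodes), 1L)
    sample(nodes, r)
  })
  covered <- unique(unlist(edges))
  missing <- setdiff(nodes, covered)
  if (length(missing)) edges[[1L]] <- union(edges[[1L]], missing)
  hypergraph(edges, nodes = nodes)
}

# random simple graph as igraph, via edge sampling
rand_test_graph <- function(n, p = 0.3) {
  A <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    if (stats::runif(1) < p) A[i, j] <- A[j, i] <- 1
  igraph::graph_from_adjacency_matrix(A, mode = "undirected")
}
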