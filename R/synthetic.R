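# Synthetic hypergraph generators -------------------------------------------

#' Worked-example hypergraph (11 nodes, 4 hyperedges)
#'
#' The small hypergraph used throughout the documentation and tests:
#' `e1 = {v1,v2,v3}`, `e2 = {v2,...,v7}`, `e3 = {v5,v6,v7,v8}`,
#' `e4 = {v4,v9,v10,v11}`.  Its overlap structure exercises every projection
#' order: three hyperedge pairs share at least one node, two pairs share two,
#' and only (e2, e3) share three, so `max_overlap()` is 3 and the 1-, 2- and
#' 3-line graphs are a star, a path plus isolate and a single edge
#' respectively.
#'
#' @return a [hypergraph()].
#' @examples
#' h <- example_hypergraph()
#' max_overlap(h)
#' @export
example_hypergraph <- function() {
  hypergraph(list(
    c("v1", "v2", "v3"),
    c("v2", "v3", "v4", "v5", "v6", "v7"),
    c("v5", "v6", "v7", "v8"),
    c("v4", "v9", "v10", "v11")
  ))
}

#' Random hypergraph
#'
#' Draws `n_hyperedges` hyperedges over `n_nodes` labelled nodes.  Each
#' cardinality is drawn from a shifted Poisson (`1 + rpois(size_mean - 1)`)
#' or a discrete power law with exponent `power_exponent` (heavy-tailed
#' cardinalities), clamped to `[1, n_nodes]`; members are sampled uniformly
#' without replacement.  Nodes left uncovered are patched into a randomly
#' chosen hyperedge so the coverage condition holds (this slightly perturbs
#' the cardinality distribution).
#'
#' @param n_nodes,n_hyperedges counts, >= 1.
#' @param size_dist `"poisson"` (default) or `"powerlaw"` cardinality
#'   distribution.
#' @param size_mean mean cardinality for the Poisson option (>= 1).
#' @param power_exponent exponent for the power-law option (> 1).
#' @param size_max upper clamp for power-law draws (default `n_nodes`).
#' @param seed optional RNG seed; a fixed seed reproduces the hypergraph
#'   exactly.
#' @return a [hypergraph()] with nodes `n1..n<N>`.
#' @export
random_hypergraph <- function(n_nodes, n_hyperedges,
                              size_dist = c("poisson", "powerlaw"),
                              size_mean = 4, power_exponent = 2.5,
                              size_max = n_nodes, seed = NULL) {
  size_dist <- match.arg(size_dist)
  stopifnot(n_nodes >= 1L, n_hyperedges >= 1L, size_mean >= 1)
  if (!is.null(seed)) set.seed(seed)
  nodes <- paste0("n", seq_len(n_nodes))
  sizes <- switch(size_dist,
    poisson = 1L + stats::rpois(n_hyperedges, size_mean - 1),
    powerlaw = {
      k <- seq_len(min(size_max, n_nodes))
      sample(k, n_hyperedges, replace = TRUE, prob = k^(-power_exponent))
    })
  sizes <- pmin(pmax(sizes, 1L), n_nodes)
  edges <- lapply(sizes, function(r) sample(nodes, r))
  # patch uncovered nodes into random hyperedges (coverage condition)
  uncovered <- setdiff(nodes, unlist(edges))
  if (length(uncovered)) {
    host <- sample.int(n_hyperedges, length(uncovered), replace = TRUE)
    for (i in seq_along(uncovered))
      edges[[host[i]]] <- union(edges[[host[i]]], uncovered[i])
  }
  hypergraph(edges, nodes = nodes)
}

#' Planted-overlap hypergraph
#'
#' A random hypergraph in which one designated hyperedge pair shares exactly
#' `overlap` nodes while every other pair shares strictly fewer, so
#' `max_overlap()` equals `overlap` by construction.  Useful for producing
#' hypergraphs with a controlled maximum projection order.
#'
#' @param n_nodes,n_hyperedges counts; `n_hyperedges >= 2`.
#' @param base_size cardinality of every hyperedge (`overlap <= base_size <=
#'   n_nodes`).
#' @param overlap planted overlap of the designated pair (the first two
#'   hyperedges), >= 1.
#' @param seed optional RNG seed.
#' @return a [hypergraph()].
#' @export
planted_overlap_hypergraph <- function(n_nodes, n_hyperedges, base_size,
                                       overlap, seed = NULL) {
  stopifnot(n_hyperedges >= 2L, overlap >= 1L, base_size >= overlap,
            base_size <= n_nodes)
  if (n_nodes < 2L * base_size - overlap)
    stop("infeasible plant: need n_nodes >= 2*base_size - overlap")
  if (!is.null(seed)) set.seed(seed)
  nodes <- paste0("n", seq_len(n_nodes))
  shared <- sample(nodes, overlap)
  rest <- setdiff(nodes, shared)
  uniq <- sample(rest, 2L * (base_size - overlap))
  e1 <- c(shared, uniq[seq_len(base_size - overlap)])
  e2 <- c(shared, uniq[-seq_len(base_size - overlap)])
  edges <- list(e1, e2)
  if (n_hyperedges > 2L) for (j in 3:n_hyperedges) {
    # rejection keeps every other pairwise overlap below the plant
    for (attempt in seq_len(1000L)) {
      cand <- sample(nodes, base_size)
      ok <- all(vapply(edges, function(e) length(intersect(e, cand)) < overlap,
                       logical(1)))
      if (ok) break
    }
    if (!ok)
      stop("infeasible spec: cannot keep non-planted overlaps below ",
           overlap, " with base_size ", base_size, " on ", n_nodes, " nodes")
    edges[[j]] <- cand
  }
  uncovered <- setdiff(nodes, unlist(edges))
  if (length(uncovered)) {
    # patch into hyperedges other than the planted pair when possible, and
    # never above the planted overlap
    host <- if (n_hyperedges > 2L)
      sample(3:n_hyperedges, length(uncovered), replace = TRUE)
    else rep(1L, length(uncovered))
    for (i in seq_along(uncovered))
      edges[[host[i]]] <- union(edges[[host[i]]], uncovered[i])
  }
  hypergraph(edges, nodes = nodes)
}

#' Dense core plus planted high-order clique
#'
#' Test-bed for order-saturation experiments: a dense random "core"
#' community (good spreaders, modest pairwise overlaps) joined with a small
#' peripheral clique of `n_planted` hyperedges over fresh nodes that all
#' share the same `planted_overlap` nodes.  The planted trio dominates every
#' line graph of order above the core's overlaps, so rankings that fuse the
#' full order range promote the peripheral nodes — which sit in a small,
#' poorly spreading satellite — while truncated order sets keep the core
#' hubs on top.
#'
#' Core pairwise overlaps are capped (by rejection) at
#' `floor(planted_overlap / 2)`, so `max_overlap()` of the result equals
#' `planted_overlap` and the upper half of the order range carries planted
#' structure only.
#'
#' @param n_core_nodes,n_core_edges size of the dense core.
#' @param core_size_mean mean core hyperedge cardinality (shifted Poisson).
#' @param n_planted number of peripheral clique hyperedges (>= 3 keeps their
#'   line graph a triangle or larger).
#' @param planted_overlap nodes shared by every pair of planted hyperedges;
#'   becomes `max_overlap()` of the result.
#' @param planted_extra unique fresh nodes per planted hyperedge.
#' @param seed optional RNG seed.
#' @return a [hypergraph()]; core nodes are `n1..`, peripheral nodes `p1..`.
#' @export
noisy_overlap_hypergraph <- function(n_core_nodes = 260L, n_core_edges = 130L,
                                     core_size_mean = 14, n_planted = 3L,
                                     planted_overlap = 12L, planted_extra = 2L,
                                     seed = NULL) {
  stopifnot(n_planted >= 2L, planted_overlap >= 2L)
  if (!is.null(seed)) set.seed(seed)
  core_nodes <- paste0("n", seq_len(n_core_nodes))
  cap <- max(1L, planted_overlap %/% 2L)    # core overlaps stay below this + 1
  edges <- list()
  for (j in seq_len(n_core_edges)) {
    for (attempt in seq_len(1000L)) {
      r <- min(n_core_nodes, 1L + stats::rpois(1L, core_size_mean - 1))
      cand <- sample(core_nodes, r)
      ok <- all(vapply(edges, function(e) length(intersect(e, cand)) <= cap,
                       logical(1)))
      if (ok) break
    }
    if (!ok)
      stop("infeasible core spec: cannot keep core overlaps at or below ", cap)
    edges[[j]] <- cand
  }
  uncovered <- setdiff(core_nodes, unlist(edges))
  if (length(uncovered)) {
    host <- sample.int(n_core_edges, length(uncovered), replace = TRUE)
    for (i in seq_along(uncovered))
      edges[[host[i]]] <- union(edges[[host[i]]], uncovered[i])
  }
  # peripheral clique on fresh labels: pairwise overlap exactly planted_overlap
  shared <- paste0("p", seq_len(planted_overlap))
  for (q in seq_len(n_planted)) {
    uniq <- paste0("p", planted_overlap + (q - 1L) * planted_extra +
                     seq_len(planted_extra))
    edges[[n_core_edges + q]] <- c(shared, uniq)
  }
  hypergraph(edges)
}
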