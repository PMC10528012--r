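# Score tables -----------------------------------------------------------

# All centralities return a `score_table`: a data.frame with columns
# node / score / rank plus a "method" attribute.  Ranks are dense positions
# under a stable descending sort (ties keep first-appearance node order), so
# every run is reproducible.

score_table <- function(h, scores, method) {
  stopifnot(length(scores) == n_nodes(h))
  ord <- order(-scores, seq_along(scores))
  rank <- integer(length(scores))
  rank[ord] <- seq_along(scores)
  structure(data.frame(node = h$nodes, score = unname(scores), rank = rank,
                       stringsAsFactors = FALSE),
            method = method,
            class = c("score_table", "data.frame"))
}

#' Ranked node list of a score table
#'
#' Nodes in descending score order; equal scores keep the hypergraph's node
#' order (stable, deterministic tie-break).
#'
#' @param t a `score_table` as returned by the `*_scores()` functions.
#' @return character vector of node labels.
#' @export
rank_nodes <- function(t) {
  stopifnot(inherits(t, "score_table") || all(c("node", "score") %in% names(t)))
  t$node[order(-t$score, seq_len(nrow(t)))]
}

#' @export
print.score_table <- function(x, n = 10L, ...) {
  cat(sprintf("Centrality scores (%s), %d nodes; top %d:\n",
              attr(x, "method") %||% "?", nrow(x), min(n, nrow(x))))
  ord <- order(x$rank)
  print.data.frame(utils::head(x[ord, ], n), row.names = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# HVC / semi-SAVC ---------------------------------------------------------

#' High-order von Neumann entropy centrality (HVC)
#'
#' For each order \eqn{s} in `orders`, the hypergraph is projected to its
#' s-line graph \eqn{L_s(H)} and the entropy change
#' \eqn{\Delta\Theta_s(e_j) = \Theta(L_s(H)) - \Theta(L_s(H) \setminus e_j)}
#' is computed for every hyperedge.  Hyperedge changes are mapped to nodes
#' with weights inversely proportional to cardinality,
#' \eqn{\Phi_s(v_i) = \sum_{j \in \Gamma(v_i)} \Delta\Theta_s(e_j)/r_j},
#' and orders are fused with harmonic weights:
#' \eqn{HVC(v_i) = \sum_{s \in orders} \Phi_s(v_i)/s}.
#'
#' The default order set is `1:max_overlap(h)` with the exact spectral
#' entropy, which is plain HVC.  Truncated order sets give the variants used
#' to study order saturation; if `max_overlap(h) == 0` (a single or pairwise
#' disjoint hyperedge set) every score is 0.
#'
#' @param h a [hypergraph()].
#' @param orders integer vector of line-graph orders (each >= 1).  Defaults
#'   to `1:max_overlap(h)`.  Orders above `max_overlap(h)` yield edgeless
#'   line graphs and contribute nothing.
#' @param entropy `"exact"` (spectral) or `"quadratic"` approximation.
#' @return a `score_table` (columns node, score, rank).
#' @export
hvc_scores <- function(h, orders = NULL, entropy = c("exact", "quadratic")) {
  entropy <- match.arg(entropy)
  smax <- max_overlap(h)
  if (is.null(orders)) {
    if (smax == 0L)
      return(score_table(h, numeric(n_nodes(h)), "HVC"))
    orders <- seq_len(smax)
  }
  orders <- unique(as.integer(orders))
  if (any(is.na(orders)) || any(orders < 1L))
    stop("'orders' must be integers >= 1")
  B <- incidence_matrix(h)               # M x N
  rj <- hyperedge_sizes(h)
  score <- numeric(n_nodes(h))
  for (s in orders) {
    A <- line_graph_adjacency(h, s)
    if (sum(A) == 0) next                # edgeless: all deltas are 0
    delta <- entropy_change_all_adj(A, entropy)
    phi <- as.numeric(Matrix::crossprod(B, delta / rj))   # Phi_s per node
    score <- score + phi / s
  }
  method <- if (identical(entropy, "exact") &&
                identical(sort(orders), seq_len(max(smax, 1L)))) "HVC"
            else sprintf("HVC[orders=%s,%s]", paste(orders, collapse = ","), entropy)
  score_table(h, score, method)
}

#' Semi-quadratic approximate von Neumann entropy centrality (semi-SAVC)
#'
#' The fast HVC variant: von Neumann entropy is replaced by its quadratic
#' approximation, and only line-graph orders up to half of the maximum
#' overlap are considered.  With `mode = "cumulative"` (default) the order
#' set is \eqn{\{1, \dots, \lfloor s_{max}/2 \rfloor\}}; with
#' `mode = "single"` only the single order \eqn{\lfloor s_{max}/2 \rfloor}
#' is used.  The half-order is floored and clamped to at least 1, so both
#' modes coincide when \eqn{\lfloor s_{max}/2 \rfloor = 1}.
#'
#' @param h a [hypergraph()].
#' @param mode `"cumulative"` or `"single"` order-set interpretation.
#' @return a `score_table`.
#' @export
semi_savc_scores <- function(h, mode = c("cumulative", "single")) {
  mode <- match.arg(mode)
  smax <- max_overlap(h)
  if (smax == 0L)
    return(score_table(h, numeric(n_nodes(h)), "semi-SAVC"))
  half <- max(1L, smax %/% 2L)
  orders <- if (mode == "cumulative") seq_len(half) else half
  out <- hvc_scores(h, orders = orders, entropy = "quadratic")
  attr(out, "method") <- sprintf("semi-SAVC[%s]", mode)
  out
}

# Baselines ----------------------------------------------------------------

#' Hyperdegree centrality (HDC)
#'
#' Number of hyperedges incident to each node, i.e. the column sums of the
#' incidence matrix.
#'
#' @param h a [hypergraph()].
#' @return a `score_table`.
#' @export
hdc_scores <- function(h) {
  score_table(h, as.numeric(hyperdegrees(h)), "HDC")
}

#' Closeness centrality (CC)
#'
#' Reciprocal of the average shortest-path distance from a node to all other
#' nodes, with distances measured on the unweighted 2-section graph.  On
#' disconnected 2-sections the plain definition is undefined; the
#' Wasserman-Faust component scaling is used instead:
#' \eqn{CC(v_i) = \frac{n_i - 1}{N - 1} \cdot \frac{n_i - 1}{\sum_{j} d_{ij}}}
#' with \eqn{n_i} the size of \eqn{v_i}'s component and the sum over that
#' component.  Isolated nodes score 0.
#'
#' @param h a [hypergraph()].
#' @return a `score_table`.
#' @export
cc_scores <- function(h) {
  g <- two_section_graph(h)
  N <- n_nodes(h)
  if (N < 2L) return(score_table(h, numeric(N), "CC"))
  D <- igraph::distances(g)               # hop distances, Inf across components
  score <- vapply(seq_len(N), function(i) {
    di <- D[i, -i]
    fin <- di[is.finite(di)]
    ni <- length(fin) + 1L                # component size
    if (ni == 1L) return(0)
    ((ni - 1) / (N - 1)) * ((ni - 1) / sum(fin))
  }, numeric(1))
  score_table(h, score, "CC")
}

#' Vector centrality (VC)
#'
#' Eigenvector centrality \eqn{c(e_j)} is computed on the 1-line graph
#' \eqn{L_1(H)} (Perron vector by power iteration, L2-normalised; isolated
#' line-graph vertices get 0).  Scores are bucketed per hyperedge
#' cardinality, \eqn{c_i^{r} = \frac{1}{r} \sum_{e_j \in \Gamma(v_i), r_j = r} c(e_j)},
#' and the node score is the one-norm of the bucket vector,
#' \eqn{VC(v_i) = \sum_r c_i^{r}}.  Node ranks are invariant to the
#' normalisation of the Perron vector, which only rescales all scores.
#'
#' @param h a [hypergraph()].
#' @param normalization `"l2"` (default) or `"max"` scaling of the Perron
#'   vector; recorded in the result's `normalization` attribute.
#' @return a `score_table`.
#' @export
vc_scores <- function(h, normalization = c("l2", "max")) {
  normalization <- match.arg(normalization)
  A1 <- line_graph_adjacency(h, 1L)
  ce <- perron_vector(A1)
  if (normalization == "max" && max(ce) > 0) ce <- ce / max(ce)
  rj <- hyperedge_sizes(h)
  B <- incidence_matrix(h)
  # bucket sum over incident hyperedges of each cardinality, weight 1/r
  score <- as.numeric(Matrix::crossprod(B, ce / rj))
  out <- score_table(h, score, "VC")
  attr(out, "normalization") <- normalization
  out
}

# Perron (leading eigen-) vector of a symmetric non-negative dense adjacency
# by power iteration: uniform positive start, L2 normalisation each sweep,
# convergence when successive iterates differ by < 1e-12 in max norm
# (cap 1e5 sweeps).  The iteration runs on A + I, which keeps the
# eigenvectors but breaks the +/-lambda degeneracy of bipartite graphs that
# would otherwise make plain power iteration oscillate.  Vertices of
# edgeless graphs get all-zero centrality; isolated vertices converge to 0.
perron_vector <- function(A, tol = 1e-12, max_iter = 1e5L) {
  n <- nrow(A)
  if (n == 0L || sum(A) == 0) return(stats::setNames(numeric(n), rownames(A)))
  x <- rep(1 / sqrt(n), n)
  for (it in seq_len(max_iter)) {
    y <- as.numeric(A %*% x) + x
    nrm <- sqrt(sum(y^2))
    if (nrm == 0) { x <- y; break }
    y <- y / nrm
    if (max(abs(y - x)) < tol) { x <- y; break }
    x <- y
  }
  stats::setNames(pmax(x, 0), rownames(A))
}

#' Sub-hypergraph centrality (SHC)
#'
#' Weighted sum of closed walks of all lengths starting and ending at the
#' node on the hypergraph adjacency matrix:
#' \eqn{SHC(v_i) = \sum_j \xi_{ij}^2 e^{\lambda_j}} over the eigenpairs of
#' \eqn{A}, i.e. the i-th diagonal entry of the matrix exponential
#' \eqn{e^{A}}.  Nodes in an edgeless hypergraph all score 1.
#'
#' @param h a [hypergraph()].
#' @return a `score_table`.
#' @export
shc_scores <- function(h) {
  A <- adjacency_matrix(h, sparse = FALSE)
  eig <- eigen(A, symmetric = TRUE)
  score <- as.numeric((eig$vectors^2) %*% exp(eig$values))
  score_table(h, score, "SHC")
}
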