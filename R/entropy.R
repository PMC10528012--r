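#' Density operator of an ordinary graph
#'
#' For a graph \eqn{G} with \eqn{n} vertices, \eqn{m \ge 1} edges, degree
#' diagonal \eqn{D} and adjacency \eqn{A}, the density operator is the scaled
#' Laplacian \eqn{\rho = (D - A) / (2m)}: a symmetric, positive semi-definite,
#' trace-one matrix whose spectrum lies in \eqn{[0, 1]}.  Rows and columns of
#' isolated vertices are all zero.
#'
#' @param g an [igraph::graph] (undirected) with at least one edge.
#' @return object of class `density_operator`: list with `matrix` (dense
#'   \eqn{\rho}), `n`, `m` and `eigenvalues` (ascending).
#' @export
density_operator <- function(g) {
  A <- graph_adjacency_dense(g)
  m <- sum(A) / 2
  if (m < 1) stop("density operator requires at least one edge (m >= 1)")
  d <- rowSums(A)
  rho <- (diag(d, nrow = nrow(A)) - A) / (2 * m)
  ev <- eigen(rho, symmetric = TRUE, only.values = TRUE)$values
  structure(list(matrix = rho, n = nrow(A), m = m,
                 eigenvalues = sort(pmax(ev, 0))),
            class = "density_operator")
}

#' @export
print.density_operator <- function(x, ...) {
  cat(sprintf("Density operator: n = %d, m = %g, trace = %.12f\n",
              x$n, x$m, sum(diag(x$matrix))))
  invisible(x)
}

#' Von Neumann entropy of a graph
#'
#' \eqn{S(\rho) = -\sum_i \lambda_i \ln \lambda_i} over the eigenvalues of
#' the density operator \eqn{\rho = L/(2m)}, with \eqn{0 \ln 0 = 0}
#' (natural log, so the result is in nats and bounded by \eqn{\ln n}).
#' An edgeless graph has no vertex-edge entanglement; its entropy is
#' defined as 0, which keeps entropy changes finite when a removal
#' disconnects everything.
#'
#' @param g an [igraph::graph] (undirected).
#' @return entropy in nats, a single non-negative number.
#' @export
von_neumann_entropy <- function(g) {
  vn_entropy_adj(graph_adjacency_dense(g))
}

#' Quadratic approximation of the von Neumann entropy
#'
#' Replaces \eqn{-\ln \rho} by its quadratic (linear-in-\eqn{\rho})
#' approximation, giving
#' \deqn{S \approx \frac{x \ln x}{x - 1}\,\mathrm{tr}[\rho(I - \rho)]
#'   = \frac{x \ln x}{x - 1}\Big(1 - \frac{1}{4 m^2}\sum_v (d_v^2 + d_v)\Big)}
#' where \eqn{x} is the number of vertices (isolates included), \eqn{m} the
#' edge count and \eqn{d_v} the vertex degrees.  Runs in \eqn{O(n)} given the
#' degree sequence; returns 0 when \eqn{m = 0} or \eqn{x \le 1}.
#'
#' @inheritParams von_neumann_entropy
#' @return approximate entropy in nats.
#' @export
von_neumann_entropy_quadratic <- function(g) {
  vn_entropy_adj(graph_adjacency_dense(g), method = "quadratic")
}

#' Entropy change under vertex removal
#'
#' \eqn{\Delta\Theta = S(G) - S(G \setminus v)} where \eqn{G \setminus v}
#' drops `v` and its incident edges; the edge count \eqn{m} is recomputed for
#' the reduced graph.  The sign is preserved (the change can in principle be
#' negative).
#'
#' @param g an [igraph::graph] (undirected).
#' @param v a vertex name or index of `g`.
#' @param method `"exact"` (spectral) or `"quadratic"` (degree-sum
#'   approximation).
#' @return entropy difference in nats.
#' @export
entropy_change <- function(g, v, method = c("exact", "quadratic")) {
  method <- match.arg(method)
  A <- graph_adjacency_dense(g)
  vi <- if (is.character(v)) match(v, rownames(A)) else as.integer(v)
  if (is.na(vi) || vi < 1L || vi > nrow(A)) stop("vertex not found: ", v)
  vn_entropy_adj(A, method) - vn_entropy_adj(A[-vi, -vi, drop = FALSE], method)
}

# ---- internal dense-adjacency kernels --------------------------------------
# The HVC inner loop removes every vertex of every s-line graph in turn;
# working on plain dense adjacency submatrices avoids igraph round-trips.

graph_adjacency_dense <- function(g) {
  if (!igraph::is_igraph(g)) stop("'g' must be an igraph graph")
  as.matrix(igraph::as_adjacency_matrix(g, type = "both", sparse = TRUE))
}

# Entropy from a dense 0/1 adjacency matrix.  Eigenvalues of rho are clipped
# at 0 to absorb -1e-16-scale numerical noise before the lambda*log(lambda)
# sum.
vn_entropy_adj <- function(A, method = c("exact", "quadratic")) {
  method <- match.arg(method)
  n <- nrow(A)
  if (n == 0L) return(0)
  d <- rowSums(A)
  m <- sum(d) / 2
  if (m == 0) return(0)
  if (method == "quadratic") {
    if (n <= 1L) return(0)
    return((n * log(n) / (n - 1)) * (1 - sum(d^2 + d) / (4 * m^2)))
  }
  L <- diag(d, nrow = n) - A
  lam <- eigen(L / (2 * m), symmetric = TRUE, only.values = TRUE)$values
  lam <- pmax(lam, 0)
  lam <- lam[lam > 0]
  -sum(lam * log(lam))
}

# Delta-Theta for every vertex of a dense adjacency: S(A) - S(A[-j,-j]).
# Vertices isolated in A have delta exactly 0 and are skipped.
entropy_change_all_adj <- function(A, method = c("exact", "quadratic")) {
  method <- match.arg(method)
  n <- nrow(A)
  S0 <- vn_entropy_adj(A, method)
  delta <- numeric(n)
  active <- which(rowSums(A) > 0)
  for (j in active)
    delta[j] <- S0 - vn_entropy_adj(A[-j, -j, drop = FALSE], method)
  names(delta) <- rownames(A)
  delta
}

#' Per-order entropy profile of a hypergraph
#'
#' For order `s`, builds \eqn{L_s(H)}, records its initial entropy
#' \eqn{\Theta(L_s(H))} and the entropy change \eqn{\Delta\Theta_s(e_j)}
#' caused by removing each hyperedge vertex in turn.
#'
#' @param h a [hypergraph()].
#' @param s line-graph order, integer >= 1.
#' @param method `"exact"` or `"quadratic"` entropy backend.
#' @return object of class `entropy_profile`: list with `s`, `theta0` and
#'   `delta` (numeric, named by hyperedge ID; 0 for isolates).
#' @export
entropy_profile <- function(h, s, method = c("exact", "quadratic")) {
  method <- match.arg(method)
  A <- line_graph_adjacency(h, s)
  structure(list(s = as.integer(s),
                 theta0 = vn_entropy_adj(A, method),
                 delta = entropy_change_all_adj(A, method)),
            class = "entropy_profile")
}

#' @export
print.entropy_profile <- function(x, ...) {
  cat(sprintf("Entropy profile, order s = %d: Theta0 = %.6f\n", x$s, x$theta0))
  print(round(x$delta, 6))
  invisible(x)
}
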