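# Evaluation instruments ----------------------------------------------------

#' Monotonicity index of a ranking
#'
#' Quantifies how tie-free a score vector is:
#' \deqn{M(R) = \Big(1 - \frac{\sum_r N_r (N_r - 1)}{N (N - 1)}\Big)^2}
#' where the \eqn{N_r} are the sizes of the score tie-groups.  \eqn{M = 1}
#' when all scores are distinct and \eqn{M = 0} when all are equal.  Scores
#' are rounded to `digits` decimals before grouping so that floating-point
#' noise does not hide genuine ties.
#'
#' @param t a `score_table` or a numeric score vector (length >= 2).
#' @param digits rounding used for tie detection (default 10).
#' @return a number in `[0, 1]`.
#' @export
monotonicity <- function(t, digits = 10L) {
  scores <- if (inherits(t, "data.frame")) t$score else as.numeric(t)
  N <- length(scores)
  if (N < 2L) stop("monotonicity requires at least 2 scores")
  Nr <- table(round(scores, digits))
  (1 - sum(Nr * (Nr - 1)) / (N * (N - 1)))^2
}

#' Pearson correlation matrix between centrality methods
#'
#' Aligns the score tables by node label and returns the method-by-method
#' Pearson correlation matrix (symmetric, unit diagonal, entries in
#' \eqn{[-1, 1]}).  A method with zero score variance has no defined
#' correlation; its entries are `NA` and a warning is raised.
#'
#' @param tables named list of `score_table`s over the same node set.
#' @return a symmetric numeric matrix with method names as dimnames.
#' @export
pearson_matrix <- function(tables) {
  if (length(tables) < 2L) stop("need at least two score tables")
  if (is.null(names(tables)) || any(!nzchar(names(tables))))
    names(tables) <- vapply(tables, function(t) attr(t, "method") %||% "?",
                            character(1))
  ref <- tables[[1L]]$node
  mat <- vapply(tables, function(t) {
    idx <- match(ref, t$node)
    if (anyNA(idx)) stop("score tables are not aligned on the same node set")
    t$score[idx]
  }, numeric(length(ref)))
  degenerate <- apply(mat, 2L, function(x) stats::sd(x) == 0)
  if (any(degenerate))
    warning("zero-variance score vector(s): ",
            paste(colnames(mat)[degenerate], collapse = ", "),
            "; correlations set to NA")
  suppressWarnings(stats::cor(mat, method = "pearson"))
}

#' Robustness under targeted node removal
#'
#' For each removal fraction `f`, deletes the `ceiling(f * N)` top-ranked
#' nodes from every hyperedge, drops emptied hyperedges, and reports the
#' node count of the largest connected component of the residual 2-section
#' graph (surviving nodes with no remaining co-membership count as
#' components of size 1).  Sizes are non-increasing in the removal fraction.
#'
#' @param h a [hypergraph()].
#' @param ranking character vector of node labels in attack order (e.g. from
#'   [rank_nodes()]).
#' @param fractions removal fractions in `(0, 1)`; default the 10/20/30
#'   percent protocol.
#' @return data.frame with columns `fraction`, `removed`, `lcc`.
#' @export
robustness_curve <- function(h, ranking, fractions = c(0.1, 0.2, 0.3)) {
  stopifnot(all(fractions > 0), all(fractions < 1))
  if (!all(ranking %in% h$nodes)) stop("ranking contains unknown nodes")
  N <- n_nodes(h)
  out <- lapply(fractions, function(f) {
    k <- min(N, max(1L, ceiling(f * N)))
    removed <- ranking[seq_len(k)]
    data.frame(fraction = f, removed = k,
               lcc = residual_lcc(h, removed))
  })
  do.call(rbind, out)
}

# Largest-connected-component size of the 2-section of h after deleting the
# given nodes from every hyperedge.
residual_lcc <- function(h, removed) {
  keep_nodes <- setdiff(h$nodes, removed)
  if (length(keep_nodes) == 0L) return(0L)
  edges <- lapply(h$hyperedges, setdiff, y = removed)
  edges <- edges[lengths(edges) > 0L]
  if (length(edges) == 0L) return(1L)     # isolated survivors only
  hr <- hypergraph(edges, nodes = intersect(h$nodes, unique(unlist(edges))))
  g <- two_section_graph(hr)
  max(igraph::components(g)$csize)        # uncovered survivors are size-1
}

#' Order-saturation sweep
#'
#' Studies how spreading influence depends on the amount of high-order line
#' graph information.  For each entry `i` of `max_orders`, nodes are ranked
#' by [hvc_scores()] with orders `1:i`, the top `top_fraction` are seeded,
#' and the mean SIR influence over `n_runs` runs is recorded.  The
#' empirical signature of order saturation is that the full order
#' `max_overlap(h)` does not attain the maximum influence over the grid.
#'
#' @param h a [hypergraph()].
#' @param max_orders integer vector of maximum orders (each in
#'   `1:max_overlap(h)`).
#' @param alpha,kappa,gamma,steps,n_runs SIR parameters (see [influence()]).
#' @param top_fraction seeded fraction of nodes (default top 1 percent).
#' @param entropy entropy backend passed to [hvc_scores()].
#' @param seed optional RNG seed for the simulations.
#' @return data.frame with columns `max_order`, `influence`, `se`; per-run
#'   prevalence matrix in attribute `per_run` (runs x orders), seed sets in
#'   attribute `seeds`.
#' @export
saturation_sweep <- function(h, max_orders, alpha = 1e-4, kappa = 1.25,
                             gamma = 0.2, steps = 5L, n_runs = 100L,
                             top_fraction = 0.01,
                             entropy = c("exact", "quadratic"),
                             seed = NULL) {
  entropy <- match.arg(entropy)
  smax <- max_overlap(h)
  max_orders <- as.integer(max_orders)
  if (any(max_orders < 1L) || any(max_orders > max(smax, 1L)))
    stop("'max_orders' must lie in 1..max_overlap(h)")
  if (!is.null(seed)) set.seed(seed)
  per_run <- matrix(NA_real_, nrow = n_runs, ncol = length(max_orders))
  seeds_used <- vector("list", length(max_orders))
  for (g_i in seq_along(max_orders)) {
    i <- max_orders[g_i]
    tab <- hvc_scores(h, orders = seq_len(i), entropy = entropy)
    sds <- top_fraction_nodes(tab, top_fraction)
    seeds_used[[g_i]] <- sds
    res <- influence(h, sds, alpha, kappa, gamma, steps, n_runs)
    per_run[, g_i] <- res$per_run
  }
  out <- data.frame(max_order = max_orders,
                    influence = colMeans(per_run),
                    se = apply(per_run, 2L, stats::sd) / sqrt(n_runs))
  attr(out, "per_run") <- per_run
  attr(out, "seeds") <- stats::setNames(seeds_used, max_orders)
  out
}
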