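# Nonlinear SIR contagion on hypergraphs -----------------------------------
#
# Discrete-time compartment model.  Each hyperedge e_j with eta_j currently
# infected members exerts an infection force beta(r_j, eta) = alpha * eta^kappa
# on its susceptible members (kappa = 1 restores the linear model); forces
# from multiple incident hyperedges add, and the sum is clamped at 1 to stay
# a valid Bernoulli probability (at alpha ~ 1e-4 the clamp is essentially
# never active).  Infected nodes recover independently with probability
# gamma per step; R is absorbing.  Updates are synchronous: all eta counts
# use the start-of-step state and nodes infected in a step cannot recover in
# that same step.

#' Initial SIR state
#'
#' @param h a [hypergraph()].
#' @param seeds character vector of seed node labels placed in state `"I"`;
#'   all other nodes start `"S"`.
#' @return named character vector over the nodes with values in
#'   `c("S", "I", "R")`.
#' @export
sir_state <- function(h, seeds) {
  seeds <- unique(as.character(seeds))
  if (length(seeds) == 0L) stop("seed set must be non-empty")
  if (!all(seeds %in% h$nodes)) stop("unknown seed node(s)")
  state <- stats::setNames(rep("S", n_nodes(h)), h$nodes)
  state[seeds] <- "I"
  state
}

#' Per-node infection probability
#'
#' For a susceptible node, the probability of infection in the coming step:
#' \eqn{p = \min(1, \sum_{e_j \ni v} \alpha\,\eta_j^{\kappa})} where
#' \eqn{\eta_j} counts the currently infected members of hyperedge \eqn{e_j}
#' (hyperedges with \eqn{\eta_j = 0} contribute nothing; recovered members do
#' not count).
#'
#' @param h a [hypergraph()].
#' @param state a state vector from [sir_state()] / [sir_step()].
#' @param node a susceptible node label.
#' @param alpha infection scale, >= 0.
#' @param kappa nonlinear exponent, > 0 (1 = linear kernel).
#' @return a probability in `[0, 1]`.
#' @export
infection_probability <- function(h, state, node, alpha, kappa) {
  if (!node %in% h$nodes) stop("unknown node: ", node)
  if (state[[node]] != "S") stop("node is not susceptible: ", node)
  stopifnot(alpha >= 0, kappa > 0)
  p <- infection_pressure(h, state, alpha, kappa)
  unname(p[node])
}

# Vector of clamped infection probabilities for all nodes (meaningful for S
# nodes; computed for everyone in one sparse product).
infection_pressure <- function(h, state, alpha, kappa, B = NULL) {
  if (is.null(B)) B <- incidence_matrix(h)
  inf <- as.numeric(state[colnames(B)] == "I")
  eta <- as.numeric(B %*% inf)              # infected members per hyperedge
  force <- ifelse(eta > 0, alpha * eta^kappa, 0)
  p <- as.numeric(Matrix::crossprod(B, force))
  stats::setNames(pmin(1, p), colnames(B))
}

#' One synchronous SIR step
#'
#' Applies the infection kernel to every susceptible node and the recovery
#' probability `gamma` to every node infected *before* the step, using one
#' uniform draw per susceptible node (in node order) followed by one per
#' infected node.  With a fixed RNG state the step is fully deterministic.
#'
#' @inheritParams infection_probability
#' @param gamma recovery probability per step, in `[0, 1]`.
#' @param B optional precomputed [incidence_matrix()] (performance).
#' @return the updated state vector.
#' @export
sir_step <- function(h, state, alpha, kappa, gamma, B = NULL) {
  stopifnot(gamma >= 0, gamma <= 1)
  s_idx <- which(state == "S")
  i_idx <- which(state == "I")
  new <- state
  if (length(s_idx) && length(i_idx) && alpha > 0) {
    p <- infection_pressure(h, state, alpha, kappa, B)[s_idx]
    hit <- stats::runif(length(s_idx)) < p
    new[s_idx[hit]] <- "I"
  }
  if (length(i_idx) && gamma > 0) {
    rec <- stats::runif(length(i_idx)) < gamma
    new[i_idx[rec]] <- "R"
  }
  new
}

#' Simulate an SIR trajectory
#'
#' Runs `steps` synchronous updates from the given seed set and records the
#' compartment counts and the prevalence \eqn{\rho(t) = (|I| + |R|)/N} after
#' every step (row `t = 0` is the initial state).  Prevalence is
#' non-decreasing because R is absorbing and I can only come from S.
#'
#' @inheritParams sir_step
#' @param seeds character vector of seed node labels.
#' @param steps number of time steps, >= 0.
#' @param seed optional RNG seed (`set.seed`) making the run reproducible.
#' @return a `sir_trajectory`: data.frame with columns `t, S, I, R,
#'   prevalence` and attributes `params` and `final_state`.
#' @export
simulate_sir <- function(h, seeds, alpha, kappa, gamma, steps = 5L,
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  B <- incidence_matrix(h)
  state <- sir_state(h, seeds)
  N <- n_nodes(h)
  rows <- vector("list", steps + 1L)
  count <- function(st, t) data.frame(
    t = t, S = sum(st == "S"), I = sum(st == "I"), R = sum(st == "R"),
    prevalence = (sum(st == "I") + sum(st == "R")) / N)
  rows[[1L]] <- count(state, 0L)
  if (steps > 0) for (t in seq_len(steps)) {
    state <- sir_step(h, state, alpha, kappa, gamma, B)
    rows[[t + 1L]] <- count(state, t)
  }
  out <- do.call(rbind, rows)
  structure(out,
            params = list(alpha = alpha, kappa = kappa, gamma = gamma,
                          steps = steps, seeds = seeds, seed = seed),
            final_state = state,
            class = c("sir_trajectory", "data.frame"))
}

#' Spreading influence of a seed set
#'
#' Mean final prevalence \eqn{\rho(t)} over `n_runs` independent stochastic
#' trajectories: the average fraction of nodes in state I or R at the last
#' time step.  Per-run values and the Monte-Carlo standard error are
#' returned for error bars and significance checks.
#'
#' @inheritParams simulate_sir
#' @param n_runs number of independent simulations, >= 1.
#' @return list with elements `mean`, `se`, `per_run` (length `n_runs`) and
#'   `params`.
#' @export
influence <- function(h, seeds, alpha, kappa, gamma, steps = 5L,
                      n_runs = 100L, seed = NULL) {
  stopifnot(n_runs >= 1L)
  if (!is.null(seed)) set.seed(seed)
  per_run <- vapply(seq_len(n_runs), function(r) {
    tr <- simulate_sir(h, seeds, alpha, kappa, gamma, steps)
    tr$prevalence[nrow(tr)]
  }, numeric(1))
  list(mean = mean(per_run),
       se = if (n_runs > 1L) stats::sd(per_run) / sqrt(n_runs) else NA_real_,
       per_run = per_run,
       params = list(alpha = alpha, kappa = kappa, gamma = gamma,
                     steps = steps, n_runs = n_runs, seeds = seeds,
                     seed = seed))
}

#' Top-fraction seed selection
#'
#' Seed-set size used by the spreading experiments:
#' `ceiling(fraction * N)`, floored at 1, taken from the top of a ranking.
#'
#' @param t a `score_table`.
#' @param fraction fraction of nodes to seed, in `(0, 1]`.
#' @return character vector of seed node labels.
#' @export
top_fraction_nodes <- function(t, fraction = 0.01) {
  stopifnot(fraction > 0, fraction <= 1)
  ranked <- rank_nodes(t)
  k <- max(1L, ceiling(fraction * length(ranked)))
  ranked[seq_len(k)]
}
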