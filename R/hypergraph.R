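#' Construct a hypergraph
#'
#' A hypergraph \eqn{H = (V, E)} is a node set \eqn{V} (\eqn{|V| = N}) together
#' with a list of non-empty hyperedges \eqn{E = \{e_1, \dots, e_M\}}, each a
#' subset of \eqn{V}.  Every node must belong to at least one hyperedge, so
#' the union of the hyperedges covers \eqn{V}.  Hyperedges are identified by
#' their list position (`e1`, `e2`, ...); duplicate hyperedges are legal and
#' kept as distinct IDs, as are hyperedges of cardinality 1.
#'
#' @param hyperedges list of character (or coercible) vectors of node labels.
#'   Duplicate labels within one hyperedge collapse to a set.
#' @param nodes optional character vector fixing the node order.  Must contain
#'   every label appearing in `hyperedges`; extra labels are rejected because
#'   they would violate the coverage condition.  Defaults to first-appearance
#'   order across the hyperedge list.
#' @return An object of class `hypergraph`: a list with elements `nodes`
#'   (character vector) and `hyperedges` (list of character vectors).
#' @examples
#' h <- hypergraph(list(c("a", "b"), c("b", "c")))
#' n_nodes(h)
#' @export
hypergraph <- function(hyperedges, nodes = NULL) {
  if (!is.list(hyperedges) || length(hyperedges) == 0L)
    stop("'hyperedges' must be a non-empty list")
  hyperedges <- lapply(hyperedges, function(e) {
    e <- as.character(e)
    e <- e[!is.na(e) & nzchar(e)]
    unique(e)
  })
  if (any(lengths(hyperedges) == 0L))
    stop("hyperedges must be non-empty")
  seen <- unique(unlist(hyperedges, use.names = FALSE))
  if (is.null(nodes)) {
    nodes <- seen
  } else {
    nodes <- as.character(nodes)
    if (anyDuplicated(nodes)) stop("node labels must be unique")
    if (!setequal(nodes, seen))
      stop("'nodes' must equal the union of the hyperedges (coverage condition)")
  }
  structure(list(nodes = nodes, hyperedges = unname(hyperedges)),
            class = "hypergraph")
}

#' @export
print.hypergraph <- function(x, ...) {
  cat(sprintf("Hypergraph: %d nodes, %d hyperedges, smax = %d\n",
              n_nodes(x), n_hyperedges(x), max_overlap(x)))
  sizes <- hyperedge_sizes(x)
  cat(sprintf("  cardinality: min %d / median %g / max %d\n",
              min(sizes), stats::median(sizes), max(sizes)))
  invisible(x)
}

#' Number of nodes / hyperedges
#'
#' @param h a [hypergraph()]
#' @return integer count.
#' @export
n_nodes <- function(h) length(h$nodes)

#' @rdname n_nodes
#' @export
n_hyperedges <- function(h) length(h$hyperedges)

#' Hyperedge IDs ("e1" ... "eM")
#' @param h a [hypergraph()]
#' @export
hyperedge_ids <- function(h) paste0("e", seq_along(h$hyperedges))

#' Hyperedge cardinalities \eqn{r_j}
#' @param h a [hypergraph()]
#' @return integer vector named by hyperedge ID.
#' @export
hyperedge_sizes <- function(h) {
  stats::setNames(lengths(h$hyperedges), hyperedge_ids(h))
}

#' Node hyperdegrees (number of incident hyperedges)
#' @param h a [hypergraph()]
#' @return integer vector named by node label.
#' @export
hyperdegrees <- function(h) {
  tab <- table(factor(unlist(h$hyperedges, use.names = FALSE), levels = h$nodes))
  stats::setNames(as.integer(tab), h$nodes)
}

#' Incident hyperedges of a node
#' @param h a [hypergraph()]
#' @param node a node label.
#' @return integer vector of hyperedge indices \eqn{\Gamma(v_i)}.
#' @export
incident_hyperedges <- function(h, node) {
  if (!node %in% h$nodes) stop("unknown node: ", node)
  which(vapply(h$hyperedges, function(e) node %in% e, logical(1)))
}

#' Incidence matrix
#'
#' The \eqn{M \times N} binary matrix \eqn{B} with \eqn{b_{ji} = 1} iff node
#' \eqn{v_i \in e_j}.  Row sums are the cardinalities \eqn{r_j}; column sums
#' are the hyperdegrees.
#'
#' @param h a [hypergraph()]
#' @param sparse return a `Matrix::sparseMatrix` (default) or a base matrix.
#' @return M x N matrix with hyperedge IDs as row names, node labels as
#'   column names.
#' @export
incidence_matrix <- function(h, sparse = TRUE) {
  M <- n_hyperedges(h)
  N <- n_nodes(h)
  j <- rep.int(seq_len(M), lengths(h$hyperedges))
  i <- match(unlist(h$hyperedges, use.names = FALSE), h$nodes)
  B <- Matrix::sparseMatrix(i = j, j = i, x = 1, dims = c(M, N),
                            dimnames = list(hyperedge_ids(h), h$nodes))
  if (sparse) B else as.matrix(B)
}

#' Adjacency matrix of the hypergraph
#'
#' \eqn{N \times N} binary matrix with \eqn{a_{ik} = 1} iff \eqn{i \neq k} and
#' some hyperedge contains both nodes; symmetric with zero diagonal.  This is
#' the adjacency matrix of the 2-section graph.
#'
#' @inheritParams incidence_matrix
#' @return N x N matrix with node labels as dimnames.
#' @export
adjacency_matrix <- function(h, sparse = TRUE) {
  B <- incidence_matrix(h)
  A <- Matrix::crossprod(B)          # N x N co-membership counts
  A@x[] <- 1
  Matrix::diag(A) <- 0
  A <- Matrix::drop0(A)
  if (sparse) A else as.matrix(A)
}

#' 2-section (clique expansion) graph
#'
#' The ordinary graph on \eqn{V} with an edge between two nodes whenever they
#' co-occur in at least one hyperedge.  Used for closeness distances and for
#' largest-connected-component robustness.
#'
#' @param h a [hypergraph()]
#' @return an [igraph::graph] with one vertex per node (isolated nodes kept).
#' @export
two_section_graph <- function(h) {
  A <- adjacency_matrix(h)
  igraph::graph_from_adjacency_matrix(A, mode = "undirected")
}

#' Overlap size of two hyperedges
#'
#' Number of nodes shared by hyperedges `j` and `k` (\eqn{|e_j \cap e_k|}).
#' The self-overlap is undefined.
#'
#' @param h a [hypergraph()]
#' @param j,k hyperedge indices (1-based), `j != k`.
#' @export
overlap_size <- function(h, j, k) {
  M <- n_hyperedges(h)
  if (j < 1L || j > M || k < 1L || k > M) stop("hyperedge index out of range")
  if (j == k) stop("self-overlap is undefined (j == k)")
  length(intersect(h$hyperedges[[j]], h$hyperedges[[k]]))
}

# M x M pairwise overlap-count matrix |e_j ∩ e_k| (diagonal = r_j).
overlap_matrix <- function(h) {
  B <- incidence_matrix(h)
  Matrix::tcrossprod(B)
}

#' Maximum pairwise hyperedge overlap
#'
#' \eqn{s_{max}}, the largest number of nodes shared by any two distinct
#' hyperedges.  Defined as 0 when `M == 1` or all hyperedges are pairwise
#' disjoint.
#'
#' @param h a [hypergraph()]
#' @return integer >= 0.
#' @export
max_overlap <- function(h) {
  if (n_hyperedges(h) < 2L) return(0L)
  P <- overlap_matrix(h)
  Matrix::diag(P) <- 0
  as.integer(max(P))
}

#' s-line graph projection
#'
#' The order-`s` line graph \eqn{L_s(H)}: an ordinary graph whose vertices
#' are the \eqn{M} hyperedges (all of them, including isolates), with an edge
#' between `e_i` and `e_j` iff \eqn{|e_i \cap e_j| \ge s}.  Edge sets are
#' nested: \eqn{L_{s+1}} edges are a subset of \eqn{L_s} edges.
#'
#' @param h a [hypergraph()]
#' @param s overlap order, integer >= 1.
#' @return an [igraph::graph] with vertices named by hyperedge ID and a graph
#'   attribute `s` recording the order.
#' @export
s_line_graph <- function(h, s) {
  if (length(s) != 1L || is.na(s) || s < 1)
    stop("'s' must be a single integer >= 1")
  A <- line_graph_adjacency(h, s)
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  igraph::graph_attr(g, "s") <- as.integer(s)
  g
}

# Dense 0/1 adjacency of L_s(H) over all M hyperedge vertices.
line_graph_adjacency <- function(h, s) {
  P <- as.matrix(overlap_matrix(h))
  diag(P) <- 0
  A <- (P >= s) + 0
  dimnames(A) <- list(hyperedge_ids(h), hyperedge_ids(h))
  A
}

# ---- readers / writers ------------------------------------------------------

#' Read a hyperedge-list file
#'
#' Primary plain-text dialect: UTF-8, one hyperedge per line, comma-separated
#' node labels with optional surrounding whitespace, `#` comment lines and
#' blank lines ignored.  Hyperedges keep file order; nodes are ordered by
#' first appearance.  Duplicate labels within a line collapse to a set;
#' duplicate hyperedges across lines are kept (and flagged with a message).
#'
#' @param path file path or a connection.
#' @return a [hypergraph()].
#' @export
read_hyperedge_list <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("no hyperedges found in input")
  edges <- lapply(strsplit(lines, ","), function(x) unique(trimws(x)[nzchar(trimws(x))]))
  if (any(lengths(edges) == 0L))
    stop("a line collapsed to the empty hyperedge")
  keys <- vapply(edges, function(e) paste(sort(e), collapse = "\r"), character(1))
  if (anyDuplicated(keys))
    message("duplicate hyperedges kept as distinct IDs: ",
            sum(duplicated(keys)), " duplicate line(s)")
  hypergraph(edges)
}

#' Write a hyperedge-list file
#'
#' @param h a [hypergraph()]
#' @param path file path or connection.
#' @export
write_hyperedge_list <- function(h, path) {
  writeLines(vapply(h$hyperedges, paste, character(1), collapse = ","), path)
  invisible(path)
}

#' Read a bipartite node-hyperedge TSV
#'
#' Second dialect: two tab-separated columns, node label then hyperedge
#' label, one incidence per line.  Hyperedge order is first appearance of the
#' hyperedge label; node order is first appearance down the node column.
#'
#' @param path file path or connection.
#' @return a [hypergraph()].
#' @export
read_bipartite_tsv <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("no incidences found in input")
  parts <- strsplit(lines, "\t")
  if (any(lengths(parts) != 2L))
    stop("each line must be 'node<TAB>hyperedge'")
  node <- trimws(vapply(parts, `[`, character(1), 1L))
  he   <- trimws(vapply(parts, `[`, character(1), 2L))
  if (any(!nzchar(node)) || any(!nzchar(he)))
    stop("empty node or hyperedge label")
  edges <- lapply(split(node, factor(he, levels = unique(he))), unique)
  hypergraph(unname(edges), nodes = unique(node))
}

#' Write a bipartite node-hyperedge TSV
#'
#' @param h a [hypergraph()]
#' @param path file path or connection.
#' @export
write_bipartite_tsv <- function(h, path) {
  ids <- hyperedge_ids(h)
  rows <- unlist(lapply(seq_along(h$hyperedges), function(j)
    paste(h$hyperedges[[j]], ids[j], sep = "\t")))
  writeLines(rows, path)
  invisible(path)
}
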