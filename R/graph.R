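#' Labelled undirected graphs
#'
#' A lightweight container for a simple undirected graph together with an
#' optional static binary group label per node (0 = blue, 1 = red). Node ids
#' are contiguous integers `1..n`. Complete graphs are stored implicitly
#' (no adjacency list), which lets the agent-based dynamics run in O(1)
#' per step on them.
#'
#' @param n Number of nodes.
#' @param edges Two-column integer matrix of undirected edges (node ids in
#'   `1..n`). Self loops are an error; duplicate and reversed pairs are
#'   collapsed.
#' @param group Optional integer vector of length `n` with values in
#'   `{0, 1}` (0 = blue, 1 = red).
#'
#' @return An object of class `labeled_graph` with fields `n`, `adj`
#'   (adjacency list, or `NULL` for implicit complete graphs), `complete`,
#'   and `group`.
#' @export
labeled_graph <- function(n, edges, group = NULL) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("'n' must be a positive integer")
  edges <- as.matrix(edges)
  if (length(edges) == 0L) {
    edges <- matrix(integer(0), ncol = 2L)
  }
  if (ncol(edges) != 2L) stop("'edges' must have two columns")
  storage.mode(edges) <- "integer"
  if (any(is.na(edges)) || any(edges < 1L) || any(edges > n))
    stop("edge endpoints must be node ids in 1..n")
  if (any(edges[, 1L] == edges[, 2L])) stop("self loops are not allowed")
  # canonical order + dedup
  a <- pmin(edges[, 1L], edges[, 2L])
  b <- pmax(edges[, 1L], edges[, 2L])
  keep <- !duplicated(a + (b - 1) * as.double(n))
  a <- a[keep]; b <- b[keep]
  adj <- build_adjacency(n, a, b)
  g <- structure(list(n = n, adj = adj, complete = FALSE, group = NULL),
                 class = "labeled_graph")
  if (!is.null(group)) g <- set_group(g, group)
  g
}

build_adjacency <- function(n, a, b) {
  adj <- split(c(b, a), factor(c(a, b), levels = seq_len(n)))
  lapply(adj, function(v) as.integer(sort(v)))
}

#' Complete graph on n nodes
#'
#' Stored implicitly: every node is adjacent to every other node.
#'
#' @param n Number of nodes (>= 2).
#' @return A `labeled_graph` (unlabelled) with `complete = TRUE`.
#' @export
complete_graph <- function(n) {
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("'n' must be at least 2")
  structure(list(n = n, adj = NULL, complete = TRUE, group = NULL),
            class = "labeled_graph")
}

#' Two-block stochastic block model graph parameterized by homophily
#'
#' Each within-group pair is linked independently with probability
#' `density * rho`, each cross-group pair with `density * (1 - rho)`.
#' At `rho = 0.5` this is a binomial (Erdos-Renyi style) random graph with
#' edge probability `density / 2`. The default `density` is chosen so the
#' expected mean degree is about 20: with `delta = 0` the dynamics depend
#' on neighbourhood composition ratios rather than absolute density, so a
#' sparse graph with the same composition semantics is preferred at desk
#' scale.
#'
#' @param n Number of nodes.
#' @param r Red fraction in `(0, 1)`; exactly `round(r * n)` nodes are red.
#' @param rho Homophily in `(0, 1)`.
#' @param density Global edge-probability multiplier `c` in `(0, 1]`;
#'   `NULL` (default) targets mean degree ~20.
#' @param group Optional explicit label vector (overrides `r`).
#' @param seed Optional RNG seed for reproducibility.
#' @return A labelled `labeled_graph`.
#' @export
sbm_graph <- function(n, r, rho, density = NULL, group = NULL, seed = NULL) {
  n <- as.integer(n)
  if (n < 2L) stop("'n' must be at least 2")
  if (rho <= 0 || rho >= 1) stop("'rho' must be in (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(group)) {
    if (r <= 0 || r >= 1) stop("'r' must be in (0, 1)")
    n_red <- as.integer(round(r * n))
    group <- c(rep(0L, n - n_red), rep(1L, n_red))
  } else {
    group <- check_group(group, n)
  }
  if (is.null(density)) {
    nb <- sum(group == 0L); nr <- n - nb
    # expected degree at c = 1, averaged over nodes
    within_pairs <- nb * (nb - 1) / 2 + nr * (nr - 1) / 2
    cross_pairs <- as.double(nb) * nr
    exp_deg_c1 <- 2 * (rho * within_pairs + (1 - rho) * cross_pairs) / n
    density <- min(1, 20 / exp_deg_c1)
  }
  if (density <= 0 || density > 1) stop("'density' must be in (0, 1]")
  p_in <- density * rho
  p_out <- density * (1 - rho)
  if (p_in > 1 || p_out > 1)
    stop("edge probabilities density*rho and density*(1-rho) must be in [0, 1]")
  from <- vector("list", n - 1L)
  to <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    j <- (i + 1L):n
    p <- ifelse(group[j] == group[i], p_in, p_out)
    hit <- runif(n - i) < p
    if (any(hit)) {
      from[[i]] <- rep.int(i, sum(hit))
      to[[i]] <- j[hit]
    }
  }
  edges <- cbind(unlist(from), unlist(to))
  if (is.null(edges)) edges <- matrix(integer(0), ncol = 2L)
  labeled_graph(n, edges, group = group)
}

check_group <- function(group, n) {
  group <- as.integer(group)
  if (length(group) != n) stop("'group' must have one label per node")
  if (any(is.na(group)) || !all(group %in% c(0L, 1L)))
    stop("group labels must be 0 (blue) or 1 (red)")
  group
}

#' Attach group labels to a graph
#' @param graph A `labeled_graph`.
#' @param group Integer vector in `{0, 1}`, one label per node.
#' @return The graph with labels set.
#' @export
set_group <- function(graph, group) {
  stopifnot(inherits(graph, "labeled_graph"))
  graph$group <- check_group(group, graph$n)
  graph
}

#' @rdname labeled_graph
#' @param graph A `labeled_graph`.
#' @export
n_nodes <- function(graph) graph$n

#' @rdname labeled_graph
#' @export
n_edges <- function(graph) {
  if (graph$complete) return(graph$n * (graph$n - 1) / 2)
  sum(lengths(graph$adj)) / 2
}

#' @rdname labeled_graph
#' @export
graph_degree <- function(graph) {
  if (graph$complete) return(rep.int(graph$n - 1L, graph$n))
  unname(lengths(graph$adj))
}

#' Neighbours of a node
#' @param graph A `labeled_graph`.
#' @param node Node id in `1..n`.
#' @return Integer vector of neighbour ids.
#' @export
neighbors_of <- function(graph, node) {
  node <- as.integer(node)
  if (is.na(node) || node < 1L || node > graph$n) stop("invalid node id")
  if (graph$complete) return(seq_len(graph$n)[-node])
  graph$adj[[node]]
}

#' Fraction of red nodes
#' @param graph A labelled `labeled_graph`.
#' @return `N_red / N`.
#' @export
red_fraction <- function(graph) {
  if (is.null(graph$group)) stop("graph has no group labels")
  mean(graph$group == 1L)
}

#' Edge list of a graph
#' @param graph A `labeled_graph`.
#' @return Two-column integer matrix, each undirected edge once with
#'   smaller id first.
#' @export
edge_matrix <- function(graph) {
  if (graph$complete) {
    n <- graph$n
    idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    return(cbind(idx[, "row"], idx[, "col"]))
  }
  from <- rep.int(seq_len(graph$n), lengths(graph$adj))
  to <- unlist(graph$adj, use.names = FALSE)
  keep <- from < to
  cbind(from[keep], to[keep])
}

#' @export
print.labeled_graph <- function(x, ...) {
  cat(sprintf("labeled_graph: %d nodes, %d edges%s\n", x$n, n_edges(x),
              if (x$complete) " (complete)" else ""))
  if (!is.null(x$group))
    cat(sprintf("  groups: %d blue, %d red (r = %.4f)\n",
                sum(x$group == 0L), sum(x$group == 1L), red_fraction(x)))
  invisible(x)
}

# error unless every node that dynamics touch has degree >= 1
check_isolates <- function(graph, tolerate = FALSE) {
  if (graph$complete) return(integer(0))
  iso <- which(lengths(graph$adj) == 0L)
  if (length(iso) && !tolerate)
    stop(sprintf(
      "graph has %d isolated node(s) (e.g. node %d); the update rule is undefined for them. Set tolerate_isolates = TRUE to skip them.",
      length(iso), iso[1L]))
  if (length(iso))
    warning(sprintf("skipping %d isolated node(s) during updates", length(iso)))
  iso
}
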