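#' Random group assignment with an exact red count
#'
#' Assigns exactly `round(r * n)` nodes to the red group (label 1),
#' chosen uniformly at random. Independent of the graph structure, so the
#' expected party assortativity is 0.
#'
#' @param graph A `labeled_graph` (or a node count).
#' @param r Red fraction in `(0, 1)`.
#' @param seed Optional RNG seed.
#' @return Integer label vector (0 = blue, 1 = red).
#' @export
assign_random <- function(graph, r, seed = NULL) {
  n <- if (inherits(graph, "labeled_graph")) graph$n else as.integer(graph)
  if (r <= 0 || r >= 1) stop("'r' must be in (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  n_red <- as.integer(round(r * n))
  group <- integer(n)
  group[sample.int(n, n_red)] <- 1L
  group
}

# same-label edge count and red degree mass, the sufficient statistics for
# the categorical assortativity coefficient
assort_stats <- function(graph, group) {
  deg <- graph_degree(graph)
  if (graph$complete) {
    nb <- sum(group == 0L); nr <- graph$n - nb
    same <- nb * (nb - 1) / 2 + nr * (nr - 1) / 2
  } else {
    same <- sum(vapply(seq_len(graph$n), function(v) {
      nb <- graph$adj[[v]]
      sum(group[nb] == group[v])
    }, numeric(1))) / 2
  }
  list(same = same, deg_red = sum(deg[group == 1L]), m = n_edges(graph))
}

assort_from_stats <- function(st) {
  if (st$m == 0) stop("graph has no edges; assortativity is undefined")
  e_same <- st$same / st$m
  a_red <- st$deg_red / (2 * st$m)
  sum_a2 <- a_red^2 + (1 - a_red)^2
  if (sum_a2 == 1) stop("only one group present among edge endpoints")
  (e_same - sum_a2) / (1 - sum_a2)
}

#' Party assortativity coefficient
#'
#' Newman's categorical attribute assortativity over edges:
#' `(sum_g e_gg - sum_g a_g^2) / (1 - sum_g a_g^2)`, where `e` is the
#' label mixing matrix with each undirected edge counted in both
#' directions and `a_g` its marginals. +1 means perfectly homophilic
#' mixing, negative values heterophilic mixing.
#'
#' @param graph A `labeled_graph` with at least one edge.
#' @param group Optional label vector (defaults to the graph's labels).
#' @return A number in `[-1, 1]`.
#' @export
party_assortativity <- function(graph, group = NULL) {
  if (is.null(group)) group <- graph$group
  if (is.null(group)) stop("no group labels supplied")
  group <- check_group(group, graph$n)
  assort_from_stats(assort_stats(graph, group))
}

#' Group assignment targeting a party assortativity
#'
#' Starts from a random assignment with exactly `round(r * n)` red nodes
#' and applies seeded simulated annealing over red/blue label swaps (which
#' preserve group sizes exactly) until the achieved assortativity is
#' within `tol` of `target`. The objective is `|achieved - target|` with
#' geometric cooling. Fails with an informative error (reporting the best
#' value reached) if the target is not achievable on the given graph.
#'
#' @param graph A `labeled_graph` with edges.
#' @param r Red fraction in `(0, 1)`.
#' @param target Target assortativity in `(-1, 1)`.
#' @param seed Optional RNG seed.
#' @param tol Acceptance tolerance (default 0.02).
#' @param max_iter Maximum number of swap proposals.
#' @param temp0,cooling Initial temperature and geometric cooling factor.
#' @return Integer label vector with attribute `achieved` (the achieved
#'   assortativity).
#' @export
assign_assortative <- function(graph, r, target, seed = NULL, tol = 0.02,
                               max_iter = 2e5, temp0 = 0.05,
                               cooling = 0.99995) {
  if (abs(target) >= 1) stop("'target' must be in (-1, 1)")
  if (!is.null(seed)) set.seed(seed)
  group <- assign_random(graph, r)
  if (graph$complete) {
    # label swaps cannot change the mixing statistics on a complete graph
    ach <- party_assortativity(graph, group)
    if (abs(ach - target) <= tol)
      return(structure(group, achieved = ach))
    stop(sprintf(
      "target assortativity %.3f is not achievable on a complete graph (fixed at %.3f by the group sizes)",
      target, ach))
  }
  deg <- graph_degree(graph)
  st <- assort_stats(graph, group)
  m <- st$m
  same <- st$same
  deg_red <- st$deg_red
  cur <- assort_from_stats(st)
  obj <- abs(cur - target)
  best <- obj
  reds <- which(group == 1L)
  blues <- which(group == 0L)
  temp <- temp0
  assort_of <- function(same, deg_red) {
    a_red <- deg_red / (2 * m)
    sum_a2 <- a_red^2 + (1 - a_red)^2
    (same / m - sum_a2) / (1 - sum_a2)
  }
  it <- 0L
  while (obj > tol / 2 && it < max_iter) {
    it <- it + 1L
    u <- reds[sample.int(length(reds), 1L)]
    v <- blues[sample.int(length(blues), 1L)]
    nb_u <- graph$adj[[u]]; nb_v <- graph$adj[[v]]
    su <- sum(group[nb_u] == 1L)       # red neighbours of the red node
    sv <- sum(group[nb_v] == 0L)       # blue neighbours of the blue node
    adj_uv <- as.integer(v %in% nb_u)
    same_new <- same + (deg[u] + deg[v] - 2 * su - 2 * sv - 2 * adj_uv)
    deg_red_new <- deg_red - deg[u] + deg[v]
    cand <- assort_of(same_new, deg_red_new)
    obj_new <- abs(cand - target)
    if (obj_new <= obj || runif(1L) < exp(-(obj_new - obj) / temp)) {
      group[u] <- 0L; group[v] <- 1L
      reds[reds == u] <- v
      blues[blues == v] <- u
      same <- same_new; deg_red <- deg_red_new
      cur <- cand; obj <- obj_new
      if (obj < best) best <- obj
    }
    temp <- temp * cooling
  }
  if (obj > tol)
    stop(sprintf(
      "could not reach target assortativity %.3f within tolerance %.3f after %d proposals (best |gap| = %.4f)",
      target, tol, it, best))
  structure(group, achieved = unname(cur))
}
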