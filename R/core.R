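#' Normalized neighbourhood composition of a node
#'
#' Splits a node's neighbours into four cells by (same group?, choice) and
#' normalizes by the node's degree, so the four fractions sum to 1.
#'
#' @param graph A labelled `labeled_graph`.
#' @param choices Integer vector in `{0, 1}`, one current choice per node.
#' @param node Node id (degree must be >= 1).
#' @return Named numeric vector `c(in0, in1, out0, out1)`.
#' @export
neighbor_stats <- function(graph, choices, node) {
  if (is.null(graph$group)) stop("graph has no group labels")
  choices <- check_choices(choices, graph$n)
  nb <- neighbors_of(graph, node)
  if (length(nb) == 0L)
    stop(sprintf("node %d is isolated; neighbourhood fractions are undefined",
                 node))
  same <- graph$group[nb] == graph$group[node]
  h <- choices[nb]
  d <- length(nb)
  c(in0 = sum(same & h == 0L) / d,
    in1 = sum(same & h == 1L) / d,
    out0 = sum(!same & h == 0L) / d,
    out1 = sum(!same & h == 1L) / d)
}

check_choices <- function(choices, n) {
  choices <- as.integer(choices)
  if (length(choices) != n) stop("'choices' must have one value per node")
  if (any(is.na(choices)) || !all(choices %in% c(0L, 1L)))
    stop("choices must be 0 or 1")
  choices
}

#' Net social drive from neighbourhood fractions
#'
#' `alpha * (in1 - in0) - beta * (out1 - out0)`: positive values push the
#' node towards choice 1, negative towards choice 0.
#'
#' @param stats Output of [neighbor_stats()].
#' @param params A [model_params()] object.
#' @return A single number in `[-1, 1]`.
#' @export
drive <- function(stats, params) {
  params <- as_model_params(params)
  unname(params$alpha * (stats[["in1"]] - stats[["in0"]]) -
           params$beta * (stats[["out1"]] - stats[["out0"]]))
}

#' Net social drive of a node
#' @inheritParams neighbor_stats
#' @param params A [model_params()] object.
#' @return A single number in `[-1, 1]`.
#' @export
node_drive <- function(graph, choices, node, params) {
  drive(neighbor_stats(graph, choices, node), params)
}

#' One application of the threshold update rule to a node
#'
#' Returns 1 if the node's drive strictly exceeds `delta`, 0 if it is
#' strictly below `-delta`, and the current choice otherwise. Comparisons
#' are exact: a drive equal to the threshold keeps the current choice.
#'
#' @inheritParams node_drive
#' @return The node's new choice (0 or 1).
#' @export
update_choice <- function(graph, choices, node, params) {
  params <- as_model_params(params)
  d <- node_drive(graph, choices, node, params)
  if (d > params$delta) 1L
  else if (d < -params$delta) 0L
  else as.integer(choices[node])
}

#' Group-level adoption fractions
#'
#' The state vector `(theta_B, theta_R)`: the fraction of blue and of red
#' nodes currently at choice 1. Both groups must be nonempty.
#'
#' @inheritParams neighbor_stats
#' @return Named numeric vector `c(theta_B, theta_R)`.
#' @export
group_state <- function(graph, choices) {
  if (is.null(graph$group)) stop("graph has no group labels")
  choices <- check_choices(choices, graph$n)
  blue <- graph$group == 0L
  if (!any(blue) || all(blue))
    stop("both groups must be nonempty to define the group state")
  c(theta_B = mean(choices[blue]), theta_R = mean(choices[!blue]))
}
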