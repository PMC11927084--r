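# Independent oracles and generators used across the suite. These read the
# model definitions literally and stay independent of the package's
# computational paths.

# random labelled graph with both groups nonempty and no isolated nodes
rand_graph <- function(n = 12, p = 0.35) {
  repeat {
    pairs <- t(utils::combn(n, 2L))
    keep <- runif(nrow(pairs)) < p
    if (!any(keep)) next
    g <- labeled_graph(n, pairs[keep, , drop = FALSE])
    if (any(lengths(g$adj) == 0L)) next
    group <- rbinom(n, 1L, 0.5)
    if (all(c(0L, 1L) %in% group)) return(set_group(g, group))
  }
}

# literal re-implementation of the node update rule: count neighbours by
# (group match, choice), normalize by degree, threshold at +/- delta
brute_update <- function(graph, choices, node, params) {
  nb <- neighbors_of(graph, node)
  d <- length(nb)
  in1 <- sum(graph$group[nb] == graph$group[node] & choices[nb] == 1L) / d
  in0 <- sum(graph$group[nb] == graph$group[node] & choices[nb] == 0L) / d
  out1 <- sum(graph$group[nb] != graph$group[node] & choices[nb] == 1L) / d
  out0 <- sum(graph$group[nb] != graph$group[node] & choices[nb] == 0L) / d
  f <- params$alpha * (in1 - in0) - params$beta * (out1 - out0)
  if (f > params$delta) 1L else if (f < -params$delta) 0L
  else as.integer(choices[node])
}

# mixing-matrix definition of the categorical assortativity coefficient:
# build the full 2x2 edge-endpoint matrix explicitly
brute_assortativity <- function(graph, group) {
  em <- edge_matrix(graph)
  e <- matrix(0, 2L, 2L)
  for (i in seq_len(nrow(em))) {
    gi <- group[em[i, 1L]] + 1L
    gj <- group[em[i, 2L]] + 1L
    e[gi, gj] <- e[gi, gj] + 1
    e[gj, gi] <- e[gj, gi] + 1
  }
  e <- e / sum(e)
  a <- rowSums(e)
  (sum(diag(e)) - sum(a^2)) / (1 - sum(a^2))
}

# vectorized fixed-step Euler integration of the group-level dynamics for
# a batch of configurations; returns snapshots every `every` steps
euler_batch <- function(thB, thR, aE, bE, r, delta, horizon, dt,
                        every = round(0.1 / dt)) {
  steps <- round(horizon / dt)
  nsnap <- steps %/% every
  SB <- matrix(NA_real_, nsnap + 1L, length(thB))
  SR <- SB
  SB[1L, ] <- thB; SR[1L, ] <- thR
  j <- 1L
  for (k in seq_len(steps)) {
    dB <- aE * (1 - r) * (2 * thB - 1) - bE * r * (2 * thR - 1)
    dR <- aE * r * (2 * thR - 1) - bE * (1 - r) * (2 * thB - 1)
    vB <- ifelse(dB > delta, 1 - thB, ifelse(dB < -delta, -thB, 0))
    vR <- ifelse(dR > delta, 1 - thR, ifelse(dR < -delta, -thR, 0))
    thB <- pmin(1, pmax(0, thB + dt * vB))
    thR <- pmin(1, pmax(0, thR + dt * vR))
    if (k %% every == 0L) {
      j <- j + 1L
      SB[j, ] <- thB; SR[j, ] <- thR
    }
  }
  list(t = seq(0, by = every * dt, length.out = j),
       B = SB[seq_len(j), , drop = FALSE], R = SR[seq_len(j), , drop = FALSE])
}

# R mirror of the sequential-update simulation loop, consuming the RNG
# stream exactly like the compiled path (one uniform draw per step)
reference_abm <- function(graph, params, choices, max_steps, record_every) {
  n <- graph$n
  h <- as.integer(choices)
  group <- graph$group
  blue <- group == 0L
  nrec <- max_steps %/% record_every + 1L
  tB <- numeric(nrec); tR <- numeric(nrec)
  tB[1L] <- mean(h[blue]); tR[1L] <- mean(h[!blue])
  j <- 1L
  for (k in seq_len(max_steps)) {
    v <- as.integer(n * runif(1L)); if (v == n) v <- n - 1L
    v <- v + 1L
    nb <- neighbors_of(graph, v)
    if (length(nb)) {
      same <- group[nb] == group[v]
      in1 <- sum(h[nb][same]); in0 <- sum(same) - in1
      out1 <- sum(h[nb][!same]); out0 <- sum(!same) - out1
      d <- params$alpha * (in1 - in0) - params$beta * (out1 - out0)
      thr <- params$delta * length(nb)
      if (d > thr) h[v] <- 1L else if (d < -thr) h[v] <- 0L
    }
    if (k %% record_every == 0L) {
      j <- j + 1L
      tB[j] <- mean(h[blue]); tR[j] <- mean(h[!blue])
    }
  }
  list(theta_B = tB, theta_R = tR, choices = h)
}

# draw a random configuration, optionally away from the phase boundaries
rand_cfg <- function(delta = 0, boundary_gap = 0) {
  repeat {
    a <- runif(1, 0.05, 1); b <- runif(1, 0.05, 1); r <- runif(1, 0.1, 0.9)
    if (boundary_gap > 0 &&
        (abs(b * (1 - r) - a * r) <= boundary_gap ||
         abs(b * r - a * (1 - r)) <= boundary_gap)) next
    return(mf_config(model_params(a, b, delta), r = r))
  }
}
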