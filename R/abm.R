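#' Initialize choices at prescribed group-level adoption fractions
#'
#' Sets exactly `round(theta0_g * N_g)` nodes of each group to choice 1,
#' chosen uniformly at random within the group.
#'
#' @param group Integer label vector (0 = blue, 1 = red); both groups must
#'   be nonempty.
#' @param theta0 Length-2 numeric `(theta_B(0), theta_R(0))` in `[0, 1]`.
#' @param seed Optional RNG seed.
#' @return Integer choice vector.
#' @export
init_choices <- function(group, theta0, seed = NULL) {
  group <- check_group(group, length(group))
  theta0 <- as.numeric(theta0)
  if (length(theta0) != 2L || any(theta0 < 0) || any(theta0 > 1))
    stop("'theta0' must be (theta_B, theta_R) in [0, 1]^2")
  if (!is.null(seed)) set.seed(seed)
  choices <- integer(length(group))
  for (g in 0:1) {
    members <- which(group == g)
    if (length(members) == 0L) stop("both groups must be nonempty")
    k <- as.integer(round(theta0[g + 1L] * length(members)))
    if (k > 0L) choices[members[sample.int(length(members), k)]] <- 1L
  }
  choices
}

graph_csr <- function(graph) {
  if (graph$complete)
    return(list(ptr = integer(1), idx = integer(0)))
  degs <- lengths(graph$adj)
  list(ptr = c(0L, cumsum(degs)),
       idx = unlist(graph$adj, use.names = FALSE) - 1L)
}

#' Run the stochastic agent-based dynamics
#'
#' Sequential random updates: at each step one node, chosen uniformly with
#' replacement, applies the threshold rule to its neighbourhood. The
#' group-level state is recorded every `record_every` steps at rescaled
#' time `t = k / N` (one time unit is N update steps, the scale on which
#' the dynamics match the mean-field ODE). With `stop_on_absorption` the
#' run halts early once a full stability sweep finds that no node's update
#' could change its choice; the recorded trajectory is then continued at
#' the absorbed state.
#'
#' @param graph A labelled `labeled_graph` with both groups nonempty.
#' @param params A [model_params()] object.
#' @param theta0 Initial group adoption `(theta_B, theta_R)` used to draw
#'   initial choices (ignored when `choices` is given).
#' @param choices Optional explicit initial choice vector.
#' @param max_steps Number of update steps (default `30 * N`).
#' @param record_every Recording stride in steps (default `max(1, N/50)`).
#' @param seed Optional RNG seed (controls both initialization and
#'   updates; identical inputs and seed give a bit-identical trajectory).
#' @param stop_on_absorption Halt early at an absorbing state.
#' @param check_every Steps between stability sweeps (default `N`).
#' @param tolerate_isolates Skip isolated nodes instead of erroring.
#' @return Data frame of class `abm_trajectory` with columns `step`, `t`,
#'   `theta_B`, `theta_R`; attributes `final_choices`, `absorbed`,
#'   `absorbed_step`, `n_flips`, `params`, `seed`.
#' @export
abm_run <- function(graph, params, theta0 = NULL, choices = NULL,
                    max_steps = NULL, record_every = NULL, seed = NULL,
                    stop_on_absorption = TRUE, check_every = NULL,
                    tolerate_isolates = FALSE) {
  stopifnot(inherits(graph, "labeled_graph"))
  params <- as_model_params(params)
  if (is.null(graph$group)) stop("graph has no group labels")
  if (!all(c(0L, 1L) %in% graph$group))
    stop("both groups must be nonempty")
  check_isolates(graph, tolerate_isolates)
  n <- graph$n
  if (is.null(max_steps)) max_steps <- 30L * n
  if (is.null(record_every)) record_every <- max(1L, n %/% 50L)
  if (is.null(check_every)) check_every <- n
  if (max_steps < 1L || record_every < 1L)
    stop("'max_steps' and 'record_every' must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(choices)) {
    if (is.null(theta0)) stop("supply either 'theta0' or 'choices'")
    choices <- init_choices(graph$group, theta0)
  } else {
    choices <- check_choices(choices, n)
  }
  csr <- graph_csr(graph)
  res <- abm_run_cpp(csr$ptr, csr$idx, graph$complete, graph$group, choices,
                     params$alpha, params$beta, params$delta,
                     as.integer(max_steps), as.integer(record_every),
                     stop_on_absorption, as.integer(check_every))
  k <- seq_len(res$n_recorded)
  out <- data.frame(step = res$step[k], t = res$step[k] / n,
                    theta_B = res$theta_B[k], theta_R = res$theta_R[k])
  structure(out, final_choices = res$choices, absorbed = res$absorbed,
            absorbed_step = res$absorbed_step, n_flips = res$n_flips,
            params = params, seed = seed,
            class = c("abm_trajectory", "data.frame"))
}

#' Percentile band of a sample
#'
#' Empirical mean and central band (default 95%) across replicate values,
#' computed columnwise. Percentile bands (type-7 quantiles) rather than a
#' normal approximation, which is robust at typical ensemble sizes.
#'
#' @param x Matrix with one row per replicate.
#' @param level Band coverage (default 0.95).
#' @return Data frame with columns `mean`, `lo`, `hi`.
#' @export
percentile_band <- function(x, level = 0.95) {
  a <- (1 - level) / 2
  data.frame(mean = colMeans(x),
             lo = apply(x, 2L, quantile, probs = a, names = FALSE),
             hi = apply(x, 2L, quantile, probs = 1 - a, names = FALSE))
}

#' Run an ensemble of independent simulations
#'
#' Runs `n_runs` replicates that differ only in their random substream
#' (per-run seeds are spawned from the master seed) and summarizes the
#' group trajectories with their mean and an empirical central 95% band.
#'
#' @inheritParams abm_run
#' @param n_runs Number of replicates (>= 2; 50 is the conventional
#'   ensemble size for confidence bands).
#' @param level Band coverage.
#' @return An object of class `abm_ensemble`: list with `t`, per-group
#'   data frames `B` and `R` (columns `mean`, `lo`, `hi`), `n_runs`,
#'   `seeds`, and the matrix attributes `runs_B`, `runs_R`.
#' @export
abm_ensemble <- function(graph, params, theta0, n_runs = 50,
                         max_steps = NULL, record_every = NULL, seed = NULL,
                         stop_on_absorption = TRUE, level = 0.95,
                         tolerate_isolates = FALSE) {
  if (n_runs < 2L) stop("'n_runs' must be at least 2")
  if (!is.null(seed)) set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n_runs)
  runs <- vector("list", n_runs)
  for (i in seq_len(n_runs)) {
    runs[[i]] <- abm_run(graph, params, theta0 = theta0,
                         max_steps = max_steps,
                         record_every = record_every, seed = seeds[i],
                         stop_on_absorption = stop_on_absorption,
                         tolerate_isolates = tolerate_isolates)
  }
  tm <- runs[[1L]]$t
  mB <- do.call(rbind, lapply(runs, function(r) r$theta_B))
  mR <- do.call(rbind, lapply(runs, function(r) r$theta_R))
  structure(list(t = tm, B = percentile_band(mB, level),
                 R = percentile_band(mR, level), n_runs = n_runs,
                 seeds = seeds, level = level),
            runs_B = mB, runs_R = mR, class = "abm_ensemble")
}

#' @export
print.abm_ensemble <- function(x, ...) {
  cat(sprintf("abm_ensemble: %d runs, %d time points, %.0f%% bands\n",
              x$n_runs, length(x$t), 100 * x$level))
  last <- length(x$t)
  cat(sprintf("  final theta_B: mean %.3f [%.3f, %.3f]\n",
              x$B$mean[last], x$B$lo[last], x$B$hi[last]))
  cat(sprintf("  final theta_R: mean %.3f [%.3f, %.3f]\n",
              x$R$mean[last], x$R$lo[last], x$R$hi[last]))
  invisible(x)
}

#' Detect trend reversals (tipping events) in a trajectory
#'
#' For mean-field trajectories the recorded switching events are used: a
#' reversal is a group's rate switching between the increasing and
#' decreasing branches. For stochastic trajectories the increments of each
#' group are smoothed with a centred running mean and sign changes of the
#' smoothed trend exceeding `min_swing` are reported.
#'
#' @param traj An `mf_trajectory` or `abm_trajectory`.
#' @param window Smoothing window (samples) for stochastic trajectories.
#' @param min_swing Minimum smoothed-increment magnitude on both sides of
#'   a sign change for it to count as a reversal.
#' @return Data frame with columns `t` and `group` ("B"/"R"), one row per
#'   reversal.
#' @export
detect_reversal <- function(traj, window = 5L, min_swing = 1e-3) {
  if (inherits(traj, "mf_trajectory")) {
    ev <- attr(traj, "events")
    out <- data.frame(t = numeric(0), group = character(0))
    for (g in c("B", "R")) {
      sub <- ev[!is.na(ev$group) & ev$group == g, , drop = FALSE]
      if (!nrow(sub)) next
      # a reversal is a switch between the two moving branches, possibly
      # through a frozen interval
      last_nonzero <- if (sub$from_region[1L] != 0L) sub$from_region[1L]
      else 0L
      for (i in seq_len(nrow(sub))) {
        s_to <- sub$to_region[i]
        if (s_to == 0L) next
        if (last_nonzero != 0L && s_to != last_nonzero)
          out <- rbind(out, data.frame(t = sub$t[i], group = g))
        last_nonzero <- s_to
      }
    }
    out <- out[order(out$t), , drop = FALSE]
    rownames(out) <- NULL
    return(out)
  }
  df <- as.data.frame(traj)
  if (nrow(df) < 3L) stop("trajectory must have at least 3 samples")
  out <- data.frame(t = numeric(0), group = character(0))
  for (g in c("B", "R")) {
    y <- df[[paste0("theta_", g)]]
    inc <- diff(y)
    sm <- as.numeric(stats::filter(inc, rep(1 / window, window),
                                   sides = 2L))
    ok <- which(!is.na(sm) & abs(sm) > min_swing / window)
    if (length(ok) < 2L) next
    s <- sign(sm[ok])
    flip <- which(diff(s) != 0)
    if (length(flip))
      out <- rbind(out, data.frame(t = df$t[ok[flip] + 1L], group = g))
  }
  out <- out[order(out$t), , drop = FALSE]
  rownames(out) <- NULL
  out
}
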