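#' Phase map: regime classification over a parameter grid
#'
#' Classifies every point of the Cartesian grid `alphas x betas x
#' r_values` (at a fixed homophily) and tabulates the share of each
#' regime.
#'
#' @param alphas,betas,r_values Numeric vectors of grid values.
#' @param rho Homophily (used in `"sbm"` mode).
#' @param delta Inertia (recorded; the classification itself concerns the
#'   no-inertia regimes).
#' @param mode `"fully_connected"` or `"sbm"`.
#' @param out Optional CSV path for the map.
#' @return Data frame with columns `alpha`, `beta`, `r`, `rho`, `case_id`
#'   and attribute `case_share` (named proportions).
#' @export
phase_map <- function(alphas, betas, r_values, rho = 0.5, delta = 0,
                      mode = "fully_connected", out = NULL) {
  grid <- expand.grid(alpha = alphas, beta = betas, r = r_values,
                      KEEP.OUT.ATTRS = FALSE)
  if (!nrow(grid)) stop("empty parameter grid")
  grid$rho <- rho
  grid$case_id <- vapply(seq_len(nrow(grid)), function(i) {
    cfg <- mf_config(model_params(grid$alpha[i], grid$beta[i], delta, rho),
                     r = grid$r[i], mode = mode)
    as.character(classify_regime(cfg)$case_id)
  }, character(1))
  attr(grid, "case_share") <- prop.table(table(grid$case_id))
  if (!is.null(out)) {
    write.csv(grid, out, row.names = FALSE, quote = FALSE)
    write_metadata(list(kind = "phase_map", mode = mode, delta = delta,
                        rho = rho, n_points = nrow(grid),
                        case_share = as.list(attr(grid, "case_share"))),
                   paste0(sub("\\.csv$", "", out), "_meta.json"))
  }
  grid
}

#' Homophily sweep: regime and limiting state as a function of rho
#'
#' For fixed behavioural parameters and group sizes, sweeps the homophily
#' level and reports the regime and the mean-field limiting state from a
#' common initial state. Decreasing `rho` amplifies out-group hate
#' (effective `beta (1 - rho)`) and damps in-group love (effective
#' `alpha rho`), so a society in the consensus regime at high homophily
#' can flip to partisan polarization as cross-group exposure grows; the
#' flip occurs where `alpha rho / (beta (1 - rho))` crosses `r / (1 - r)`.
#'
#' @param alpha,beta,delta Behavioural parameters.
#' @param r Red fraction.
#' @param rhos Homophily values to sweep.
#' @param theta0 Common initial state.
#' @param out Optional CSV path.
#' @return Data frame with columns `rho`, `case_id`, `theta_B_lim`,
#'   `theta_R_lim`.
#' @export
homophily_sweep <- function(alpha, beta, r, rhos, theta0 = c(0.8, 0.8),
                            delta = 0, out = NULL) {
  rows <- lapply(rhos, function(rho) {
    cfg <- mf_config(model_params(alpha, beta, delta, rho), r = r,
                     mode = "sbm")
    lim <- limiting_state(theta0, cfg)
    data.frame(rho = rho,
               case_id = as.character(classify_regime(cfg)$case_id),
               theta_B_lim = lim[["theta_B"]],
               theta_R_lim = lim[["theta_R"]])
  })
  res <- do.call(rbind, rows)
  if (!is.null(out)) write.csv(res, out, row.names = FALSE, quote = FALSE)
  res
}

#' Write small deterministic fixture graphs and a golden trajectory
#'
#' Produces, under `dir`: `two_cliques.txt` (two 10-cliques joined by one
#' bridge edge) with clique-aligned labels, `er.txt` (a neutral-homophily
#' binomial graph), `sbm.txt` (a strongly homophilic block model) with
#' label files, and `golden_case1.csv`, the event-driven consensus
#' trajectory for a reference case-1 configuration. Everything is seeded,
#' so repeated calls are bit-identical.
#'
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_fixtures <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  p <- function(f) file.path(dir, f)
  # two cliques + one bridge
  cl <- function(off) t(utils::combn(off + 1:10, 2L))
  g2 <- labeled_graph(20, rbind(cl(0L), cl(10L), c(1L, 11L)),
                      group = rep(c(0L, 1L), each = 10L))
  write_edgelist(g2, p("two_cliques.txt"))
  write_labels(g2$group, p("two_cliques_labels.csv"))
  er <- sbm_graph(60, r = 0.5, rho = 0.5, density = 0.4, seed = 101L)
  write_edgelist(er, p("er.txt"))
  write_labels(er$group, p("er_labels.csv"))
  sbm <- sbm_graph(80, r = 0.5, rho = 0.9, density = 0.4, seed = 202L)
  write_edgelist(sbm, p("sbm.txt"))
  write_labels(sbm$group, p("sbm_labels.csv"))
  cfg <- mf_config(model_params(0.8, 0.4), r = 0.5)
  tr <- mf_integrate(c(0.8, 0.8), cfg, horizon = 10, sample_dt = 0.25)
  write_trajectory(tr, p("golden_case1.csv"))
  paths <- c(p("two_cliques.txt"), p("two_cliques_labels.csv"), p("er.txt"),
             p("er_labels.csv"), p("sbm.txt"), p("sbm_labels.csv"),
             p("golden_case1.csv"))
  invisible(paths)
}

# representative parameter/initial-state sets behind each figure recipe
recipe_params <- function() {
  list(
    fig1 = list(
      case1 = list(alpha = 0.8, beta = 0.4, r = 0.5),
      case2 = list(alpha = 0.6, beta = 0.5, r = 0.65),
      case3 = list(alpha = 0.6, beta = 0.5, r = 0.35),
      case4 = list(alpha = 0.3, beta = 0.9, r = 0.5)),
    fig2 = list(alpha = 0.8, beta = 0.7, r = 0.65, rhos = c(0.7, 0.5)),
    # three qualitative tipping scenarios from group-dependent starts
    fig3 = list(
      i = list(alpha = 0.7, beta = 0.5, r = 0.7, theta0 = c(0.9, 0.7)),
      ii = list(alpha = 0.5, beta = 0.7, r = 0.65, theta0 = c(0.9, 0.7)),
      iii = list(alpha = 0.5, beta = 0.7, r = 0.35, theta0 = c(0.7, 0.9))),
    fig6 = list(alpha = 0.7, beta = 0.5, r = 0.53,
                assortativity = c(homophilic = 0.58, neutral = 0.00,
                                  heterophilic = -0.13),
                theta0 = c(0.8, 0.8))
  )
}

ensure_graph <- function(graph_path, synthetic_fallback, n, seed,
                         rho = 0.5, r = 0.5) {
  if (!is.null(graph_path)) return(read_edgelist(graph_path))
  if (!synthetic_fallback)
    stop("no graph file given; pass 'graph_path' or set synthetic_fallback = TRUE for a generated SBM stand-in")
  sbm_graph(n, r = r, rho = rho, seed = seed)
}

#' Reproduce a figure-style experiment
#'
#' Runs the recipe behind one of the six headline experiment designs and
#' writes trajectory/ensemble CSVs plus a JSON metadata sidecar to
#' `out_dir`:
#' * `fig1`: mean-field trajectories from `theta0 = (0.8, 0.8)` for one
#'   representative parameter set per regime (consensus, both partisan
#'   regimes, nonpartisan).
#' * `fig2`: the homophily flip at `alpha = 0.8, beta = 0.7, r = 0.65`:
#'   consensus at `rho = 0.7`, partisan split at `rho = 0.5`.
#' * `fig3`: three group-dependent starts where one group reverses its
#'   trend at a switching manifold.
#' * `fig4` / `fig5`: stochastic ensembles (default 50 runs, 95% bands)
#'   of the `fig1` / `fig3` configurations on a supplied edge-list graph,
#'   or on a generated neutral SBM stand-in, with the mean-field endpoint
#'   gap reported.
#' * `fig6`: homophilic / neutral / heterophilic label assignments
#'   (target assortativities 0.58, 0.00, -0.13) at `r = 0.53`,
#'   `alpha = 0.7, beta = 0.5`, each run as an ensemble.
#'
#' @param figure One of `"fig1"` ... `"fig6"`.
#' @param out_dir Output directory.
#' @param graph_path Optional edge-list file for `fig4`-`fig6`.
#' @param synthetic_fallback Generate an SBM stand-in when no graph file
#'   is given (default TRUE).
#' @param n Stand-in graph size.
#' @param n_runs Ensemble size.
#' @param seed Master seed.
#' @return Invisibly, a list with the per-panel results (trajectories,
#'   ensembles, endpoint gaps).
#' @export
reproduce_figure <- function(figure, out_dir, graph_path = NULL,
                             synthetic_fallback = TRUE, n = 1000,
                             n_runs = 50, seed = 1) {
  figure <- match.arg(figure, paste0("fig", 1:6))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rp <- recipe_params()
  set.seed(seed)
  meta <- list(kind = "reproduce", figure = figure, seed = seed)
  res <- list()
  p <- function(f) file.path(out_dir, f)

  if (figure == "fig1") {
    for (nm in names(rp$fig1)) {
      pr <- rp$fig1[[nm]]
      cfg <- mf_config(model_params(pr$alpha, pr$beta), r = pr$r)
      tr <- mf_integrate(c(0.8, 0.8), cfg)
      write_trajectory(tr, p(sprintf("fig1_%s.csv", nm)))
      res[[nm]] <- tr
    }
    meta$params <- rp$fig1
  } else if (figure == "fig2") {
    pr <- rp$fig2
    for (rho in pr$rhos) {
      cfg <- mf_config(model_params(pr$alpha, pr$beta, rho = rho),
                       r = pr$r, mode = "sbm")
      tr <- mf_integrate(c(0.8, 0.8), cfg)
      nm <- sprintf("rho_%g", rho)
      write_trajectory(tr, p(sprintf("fig2_%s.csv", nm)))
      res[[nm]] <- list(trajectory = tr,
                        case_id = classify_regime(cfg)$case_id)
    }
    meta$params <- pr[c("alpha", "beta", "r")]
  } else if (figure == "fig3") {
    for (nm in names(rp$fig3)) {
      pr <- rp$fig3[[nm]]
      cfg <- mf_config(model_params(pr$alpha, pr$beta), r = pr$r)
      tr <- mf_integrate(pr$theta0, cfg)
      write_trajectory(tr, p(sprintf("fig3_%s.csv", nm)))
      res[[nm]] <- list(trajectory = tr, reversals = detect_reversal(tr),
                        manifolds = switching_manifolds(cfg))
    }
    meta$params <- rp$fig3
  } else if (figure %in% c("fig4", "fig5")) {
    sets <- if (figure == "fig4") rp$fig1 else rp$fig3
    graph <- ensure_graph(graph_path, synthetic_fallback, n, seed)
    gaps <- list()
    for (nm in names(sets)) {
      pr <- sets[[nm]]
      theta0 <- if (is.null(pr$theta0)) c(0.8, 0.8) else pr$theta0
      graph <- set_group(graph, assign_random(graph, pr$r))
      pars <- model_params(pr$alpha, pr$beta)
      ens <- abm_ensemble(graph, pars, theta0, n_runs = n_runs,
                          max_steps = 15L * graph$n,
                          seed = seed + match(nm, names(sets)))
      cfg <- mf_config(pars, r = red_fraction(graph))
      mf <- mf_integrate(theta0, cfg, horizon = max(ens$t))
      mf_end <- attr(mf, "theta_final")
      last <- length(ens$t)
      gap <- c(theta_B = abs(ens$B$mean[last] - mf_end[["theta_B"]]),
               theta_R = abs(ens$R$mean[last] - mf_end[["theta_R"]]))
      write.csv(data.frame(t = ens$t, mean_B = ens$B$mean, lo_B = ens$B$lo,
                           hi_B = ens$B$hi, mean_R = ens$R$mean,
                           lo_R = ens$R$lo, hi_R = ens$R$hi),
                p(sprintf("%s_%s_ensemble.csv", figure, nm)),
                row.names = FALSE, quote = FALSE)
      write_trajectory(mf, p(sprintf("%s_%s_meanfield.csv", figure, nm)))
      gaps[[nm]] <- gap
      res[[nm]] <- list(ensemble = ens, meanfield = mf, endpoint_gap = gap)
    }
    meta$endpoint_gaps <- gaps
    meta$graph <- list(n = graph$n, m = n_edges(graph),
                       source = if (is.null(graph_path)) "synthetic sbm stand-in" else graph_path)
  } else { # fig6
    pr <- rp$fig6
    graph <- ensure_graph(graph_path, synthetic_fallback, n, seed,
                          rho = 0.85, r = 0.5)
    gaps <- list()
    for (nm in names(pr$assortativity)) {
      target <- pr$assortativity[[nm]]
      group <- if (nm == "neutral") assign_random(graph, pr$r, seed = seed)
      else assign_assortative(graph, pr$r, target, seed = seed)
      graph <- set_group(graph, group)
      ach <- party_assortativity(graph)
      pars <- model_params(pr$alpha, pr$beta)
      ens <- abm_ensemble(graph, pars, pr$theta0, n_runs = n_runs,
                          max_steps = 15L * graph$n,
                          seed = seed + match(nm, names(pr$assortativity)))
      cfg <- mf_config(pars, r = red_fraction(graph))
      mf <- mf_integrate(pr$theta0, cfg, horizon = max(ens$t))
      mf_end <- attr(mf, "theta_final")
      last <- length(ens$t)
      gap <- c(theta_B = abs(ens$B$mean[last] - mf_end[["theta_B"]]),
               theta_R = abs(ens$R$mean[last] - mf_end[["theta_R"]]))
      write_labels(group, p(sprintf("fig6_%s_labels.csv", nm)))
      write.csv(data.frame(t = ens$t, mean_B = ens$B$mean, lo_B = ens$B$lo,
                           hi_B = ens$B$hi, mean_R = ens$R$mean,
                           lo_R = ens$R$lo, hi_R = ens$R$hi),
                p(sprintf("fig6_%s_ensemble.csv", nm)),
                row.names = FALSE, quote = FALSE)
      gaps[[nm]] <- list(achieved_assortativity = ach, endpoint_gap = gap)
      res[[nm]] <- list(ensemble = ens, achieved_assortativity = ach,
                        endpoint_gap = gap)
    }
    meta$params <- pr[c("alpha", "beta", "r")]
    meta$assignments <- gaps
    meta$graph <- list(n = graph$n, m = n_edges(graph),
                       source = if (is.null(graph_path)) "synthetic sbm stand-in" else graph_path)
  }
  write_metadata(meta, p(sprintf("%s_meta.json", figure)))
  invisible(res)
}
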