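#' Mean-field configuration
#'
#' The group-level limit dynamics of the model track
#' `theta = (theta_B, theta_R)`, the choice-1 fractions of the blue and red
#' groups. Each component grows at rate `1 - theta` while its group drive
#' exceeds `delta`, shrinks at rate `-theta` while the drive is below
#' `-delta`, and is frozen otherwise. On a two-community graph with
#' homophily `rho`, in-group love is amplified and out-group hate damped:
#' the effective parameters are `alpha * rho` and `beta * (1 - rho)`.
#'
#' @param params A [model_params()] object.
#' @param r Red-group fraction in `(0, 1)`.
#' @param mode `"fully_connected"` (ignore `rho`) or `"sbm"` (apply the
#'   homophily rescaling).
#' @param red_drive `"symmetric"` (default) scales the red in-group term by
#'   the red group size `r`, mirroring the blue drive's `1 - r` factor;
#'   `"unscaled"` omits that factor (kept for comparison only: the
#'   unscaled variant does not reproduce the diagonal phase boundaries).
#' @return An object of class `mf_config`.
#' @export
mf_config <- function(params, r, mode = c("fully_connected", "sbm"),
                      red_drive = c("symmetric", "unscaled")) {
  params <- as_model_params(params)
  mode <- match.arg(mode)
  red_drive <- match.arg(red_drive)
  if (!is.numeric(r) || length(r) != 1L || r <= 0 || r >= 1)
    stop("'r' must be a single number in (0, 1)")
  structure(list(params = params, r = r, mode = mode, red_drive = red_drive),
            class = "mf_config")
}

#' @export
print.mf_config <- function(x, ...) {
  ep <- effective_params(x)
  cat(sprintf("mf_config: mode = %s, r = %g, delta = %g\n",
              x$mode, x$r, x$params$delta))
  cat(sprintf("  effective alpha = %g, beta = %g (red drive: %s)\n",
              ep[["alpha"]], ep[["beta"]], x$red_drive))
  invisible(x)
}

#' Effective (homophily-rescaled) behavioural parameters
#'
#' In `"sbm"` mode returns `(alpha * rho, beta * (1 - rho))`; in
#' `"fully_connected"` mode the parameters are unchanged. With `delta = 0`
#' the rescaling at `rho = 0.5` multiplies both drives by 0.5 and leaves
#' every sign, hence every trajectory, unchanged.
#'
#' @param cfg An [mf_config()] object.
#' @return Named numeric vector `c(alpha, beta)`.
#' @export
effective_params <- function(cfg) {
  p <- cfg$params
  if (cfg$mode == "sbm")
    c(alpha = p$alpha * p$rho, beta = p$beta * (1 - p$rho))
  else c(alpha = p$alpha, beta = p$beta)
}

# linear coefficients of the two drives:
# d_g(theta) = cB[g] * theta_B + cR[g] * theta_R + c0[g]
drive_coefs <- function(cfg) {
  ep <- effective_params(cfg)
  aE <- ep[["alpha"]]; bE <- ep[["beta"]]; r <- cfg$r
  cB <- c(2 * aE * (1 - r), -2 * bE * (1 - r))
  cR <- c(-2 * bE * r, if (cfg$red_drive == "symmetric") 2 * aE * r else 2 * aE)
  c0 <- -(cB + cR) / 2
  list(cB = cB, cR = cR, c0 = c0)
}

#' Group drives at a mean-field state
#'
#' `drive_B = a_e (1-r)(2 theta_B - 1) - b_e r (2 theta_R - 1)` and the
#' symmetric red counterpart
#' `drive_R = a_e r (2 theta_R - 1) - b_e (1-r)(2 theta_B - 1)`,
#' where `(a_e, b_e)` are the effective parameters.
#'
#' @param theta Numeric length-2 state `(theta_B, theta_R)` in the unit
#'   square.
#' @param cfg An [mf_config()] object.
#' @return Named numeric vector `c(drive_B, drive_R)`.
#' @export
mf_drives <- function(theta, cfg) {
  co <- drive_coefs(cfg)
  c(drive_B = co$cB[1L] * theta[1L] + co$cR[1L] * theta[2L] + co$c0[1L],
    drive_R = co$cB[2L] * theta[1L] + co$cR[2L] * theta[2L] + co$c0[2L])
}

# region code per group: +1 drive > delta, -1 drive < -delta, 0 otherwise
regions_raw <- function(d, delta) {
  ifelse(d > delta, 1L, ifelse(d < -delta, -1L, 0L))
}

#' Right-hand side of the mean-field ODE
#'
#' @inheritParams mf_drives
#' @return Named numeric vector `c(dtheta_B, dtheta_R)`.
#' @export
mf_rhs <- function(theta, cfg) {
  d <- mf_drives(theta, cfg)
  reg <- regions_raw(d, cfg$params$delta)
  v <- ifelse(reg == 1L, 1 - theta, ifelse(reg == -1L, -theta, 0))
  c(dtheta_B = unname(v[1L]), dtheta_R = unname(v[2L]))
}

# Resolve region codes at a state, disambiguating drives that sit exactly
# on a +/-delta threshold by requiring the chosen flow to be consistent
# with the threshold side it claims (frozen is preferred when consistent,
# which both keeps exact fixed points stationary and implements the
# freeze-while-pinned convention on a switching manifold).
resolve_regions <- function(theta, cfg, tol = 1e-12, slope_tol = 1e-10) {
  delta <- cfg$params$delta
  co <- drive_coefs(cfg)
  d <- mf_drives(theta, cfg)
  opts <- vector("list", 2L)
  for (g in 1:2) {
    if (abs(d[g] - delta) <= tol || abs(d[g] + delta) <= tol) {
      opts[[g]] <- if (delta <= tol) c(0L, 1L, -1L)
      else if (abs(d[g] - delta) <= tol) c(0L, 1L) else c(0L, -1L)
    } else {
      opts[[g]] <- regions_raw(d[g], delta)
    }
  }
  borderline <- lengths(opts) > 1L
  if (!any(borderline))
    return(list(region = c(opts[[1L]], opts[[2L]]), slide = FALSE))
  combos <- expand.grid(g1 = opts[[1L]], g2 = opts[[2L]],
                        KEEP.OUT.ATTRS = FALSE)
  for (i in seq_len(nrow(combos))) {
    reg <- c(combos$g1[i], combos$g2[i])
    targ <- ifelse(reg == 1L, 1, ifelse(reg == -1L, 0, theta))
    # d_g(s) = A_g + B_g exp(-s); initial slope is -B_g
    slope <- -c(co$cB[1L] * (theta[1L] - targ[1L]) +
                  co$cR[1L] * (theta[2L] - targ[2L]),
                co$cB[2L] * (theta[1L] - targ[1L]) +
                  co$cR[2L] * (theta[2L] - targ[2L]))
    ok <- TRUE
    for (g in 1:2) {
      if (!borderline[g]) next
      at_plus <- abs(d[g] - delta) <= tol
      ok_g <- if (reg[g] == 1L) slope[g] > slope_tol
      else if (reg[g] == -1L) slope[g] < -slope_tol
      else if (delta <= tol) abs(slope[g]) <= slope_tol
      else if (at_plus) slope[g] <= slope_tol
      else slope[g] >= -slope_tol
      if (!ok_g) { ok <- FALSE; break }
    }
    if (ok) return(list(region = reg, slide = FALSE))
  }
  # no self-consistent assignment: freeze the pinned components (sliding)
  reg <- c(opts[[1L]][1L], opts[[2L]][1L])
  reg[borderline] <- 0L
  list(region = reg, slide = TRUE)
}

#' Integrate the mean-field dynamics exactly, region by region
#'
#' Between switching events each component follows a closed-form
#' exponential (`theta -> 1` at rate `1 - theta`, `theta -> 0` at rate
#' `theta`, or constant), and each group drive along the flow has the form
#' `A + B exp(-s)`, so region-exit times are obtained in closed form from
#' a logarithm. The trajectory is recorded on a regular sampling grid plus
#' at every switching event.
#'
#' @param theta0 Initial state `(theta_B, theta_R)` in the unit square.
#' @param cfg An [mf_config()] object.
#' @param horizon Integration horizon (model time units).
#' @param sample_dt Spacing of the recording grid.
#' @param max_events Safety cap on the number of switching events.
#' @return A data frame of class `mf_trajectory` with columns `t`,
#'   `theta_B`, `theta_R`, `region_B`, `region_R`, and attributes
#'   `events` (data frame: `t`, `group`, `from_region`, `to_region`,
#'   `kind`), `theta_final`, `limit`, `converged`, `cfg`.
#' @examples
#' cfg <- mf_config(model_params(0.8, 0.4), r = 0.5)
#' tr <- mf_integrate(c(0.8, 0.8), cfg)
#' attr(tr, "theta_final")  # consensus at (1, 1)
#' @export
mf_integrate <- function(theta0, cfg, horizon = 40, sample_dt = 0.05,
                         max_events = 500) {
  stopifnot(inherits(cfg, "mf_config"))
  theta0 <- as.numeric(theta0)
  if (length(theta0) != 2L || any(!is.finite(theta0)) ||
      any(theta0 < 0) || any(theta0 > 1))
    stop("'theta0' must be a length-2 state in the unit square")
  if (horizon <= 0) stop("'horizon' must be positive")
  co <- drive_coefs(cfg)
  delta <- cfg$params$delta
  theta <- theta0
  t_now <- 0
  rows <- vector("list", 256L)
  nrow_used <- 0L
  ev <- list()
  add_row <- function(t, th, reg) {
    nrow_used <<- nrow_used + 1L
    if (nrow_used > length(rows)) length(rows) <<- 2L * nrow_used
    rows[[nrow_used]] <<- c(t, th, reg)
  }
  if (sample_dt <= 0) stop("'sample_dt' must be positive")
  res <- resolve_regions(theta, cfg)
  reg <- res$region
  n_ev <- 0L
  tiny_steps <- 0L
  converged <- FALSE
  limit <- theta
  repeat {
    targ <- ifelse(reg == 1L, 1, ifelse(reg == -1L, 0, theta))
    add_row(t_now, theta, reg)
    if (all(reg == 0L)) { converged <- TRUE; limit <- theta; break }
    # drive along the flow: d_g(s) = A_g + B_g exp(-s)
    A <- c(co$cB[1L] * targ[1L] + co$cR[1L] * targ[2L] + co$c0[1L],
           co$cB[2L] * targ[1L] + co$cR[2L] * targ[2L] + co$c0[2L])
    B <- c(co$cB[1L] * (theta[1L] - targ[1L]) +
             co$cR[1L] * (theta[2L] - targ[2L]),
           co$cB[2L] * (theta[1L] - targ[1L]) +
             co$cR[2L] * (theta[2L] - targ[2L]))
    s_star <- Inf
    for (g in 1:2) {
      for (tau in unique(c(delta, -delta))) {
        if (abs(B[g]) < 1e-300) next
        x <- (tau - A[g]) / B[g]
        if (x > 0 && x < 1) {
          s <- -log(x)
          if (s > 1e-13 && s < s_star) s_star <- s
        }
      }
    }
    s_adv <- min(s_star, horizon - t_now)
    # sample grid points strictly inside the segment
    k0 <- ceiling((t_now + 1e-12) / sample_dt)
    k1 <- floor((t_now + s_adv - 1e-12) / sample_dt)
    if (k1 >= k0) {
      for (tt in (k0:k1) * sample_dt) {
        e <- exp(-(tt - t_now))
        add_row(tt, targ + (theta - targ) * e, reg)
      }
    }
    theta_new <- targ + (theta - targ) * exp(-s_adv)
    t_now <- t_now + s_adv
    theta <- pmin(1, pmax(0, theta_new))
    if (t_now >= horizon - 1e-13) {
      # reached the horizon (with or without a further event ahead)
      limit <- ifelse(reg == 0L, theta, targ)
      converged <- all(reg == 0L) || all(abs(theta - limit) < 1e-9)
      add_row(t_now, theta, reg)
      break
    }
    # switching event
    n_ev <- n_ev + 1L
    if (n_ev > max_events)
      stop("mean-field event loop exceeded 'max_events'; the trajectory may be in a sliding mode along a switching manifold")
    if (s_adv < 1e-11) tiny_steps <- tiny_steps + 1L else tiny_steps <- 0L
    if (tiny_steps > 10L)
      stop("mean-field integrator is not advancing (repeated zero-length events); possible sliding mode")
    res <- resolve_regions(theta, cfg)
    reg_new <- res$region
    for (g in which(reg_new != reg)) {
      ev[[length(ev) + 1L]] <- data.frame(
        t = t_now, group = c("B", "R")[g], from_region = reg[g],
        to_region = reg_new[g], kind = if (res$slide) "slide" else "cross",
        stringsAsFactors = FALSE)
    }
    if (all(reg_new == reg)) {
      # drive touched a threshold without a region change (grazing)
      ev[[length(ev) + 1L]] <- data.frame(
        t = t_now, group = NA_character_, from_region = NA_integer_,
        to_region = NA_integer_, kind = "graze", stringsAsFactors = FALSE)
    }
    reg <- reg_new
  }
  out <- do.call(rbind, rows[seq_len(nrow_used)])
  out <- data.frame(t = out[, 1L], theta_B = out[, 2L], theta_R = out[, 3L],
                    region_B = as.integer(out[, 4L]),
                    region_R = as.integer(out[, 5L]))
  # drop duplicated time stamps created by event bookkeeping
  out <- out[!duplicated(sprintf("%.12f", out$t), fromLast = TRUE), ]
  rownames(out) <- NULL
  events <- if (length(ev)) do.call(rbind, ev)
  else data.frame(t = numeric(0), group = character(0),
                  from_region = integer(0), to_region = integer(0),
                  kind = character(0), stringsAsFactors = FALSE)
  structure(out, events = events, theta_final = c(theta_B = theta[1L],
                                                  theta_R = theta[2L]),
            limit = c(theta_B = limit[1L], theta_R = limit[2L]),
            converged = converged, cfg = cfg,
            class = c("mf_trajectory", "data.frame"))
}

#' Fixed-step (Euler) integrator for the mean-field dynamics
#'
#' A plain forward-Euler reference integrator. Much slower and less exact
#' than [mf_integrate()]; intended for cross-validation.
#'
#' @inheritParams mf_integrate
#' @param dt Euler step size.
#' @return Data frame with columns `t`, `theta_B`, `theta_R`.
#' @export
mf_integrate_fixed <- function(theta0, cfg, horizon = 10, dt = 1e-3) {
  n <- ceiling(horizon / dt)
  theta <- as.numeric(theta0)
  keep <- max(1L, floor(n / 2000))
  ts <- numeric(0); xs <- NULL
  rec_t <- numeric(floor(n / keep) + 2L)
  rec_x <- matrix(0, floor(n / keep) + 2L, 2L)
  j <- 1L; rec_t[1L] <- 0; rec_x[1L, ] <- theta
  for (k in seq_len(n)) {
    theta <- theta + dt * mf_rhs(theta, cfg)
    theta <- pmin(1, pmax(0, theta))
    if (k %% keep == 0L || k == n) {
      j <- j + 1L; rec_t[j] <- k * dt; rec_x[j, ] <- theta
    }
  }
  data.frame(t = rec_t[seq_len(j)], theta_B = rec_x[seq_len(j), 1L],
             theta_R = rec_x[seq_len(j), 2L])
}

#' Classify the asymptotic regime of a configuration
#'
#' With no inertia and a group-independent initial state, the long-run
#' outcome is decided by how the group-size ratio `r / (1 - r)` compares
#' with the effective love/hate ratios `a_e / b_e` and `b_e / a_e`:
#' * case 1 (consensus): `b_e/a_e < r/(1-r) < a_e/b_e`;
#' * case 2 (partisan, red majority side): `r/(1-r)` above both ratios;
#' * case 3 (partisan, blue majority side): `r/(1-r)` below both ratios;
#' * case 4 (nonpartisan): `b_e/a_e > r/(1-r) > a_e/b_e`.
#' Comparisons are evaluated by cross-multiplication, so `b_e = 0` is
#' handled without division. Equality in any comparison yields the
#' non-generic `"boundary"` case.
#'
#' @param cfg An [mf_config()] object.
#' @return An object of class `regime`: list with `case_id` (1, 2, 3, 4
#'   or `"boundary"`) and `description`.
#' @export
classify_regime <- function(cfg) {
  ep <- effective_params(cfg)
  aE <- ep[["alpha"]]; bE <- ep[["beta"]]; r <- cfg$r
  if (aE == 0 && bE == 0)
    stop("both effective parameters are zero: no dynamics to classify")
  # L: b/a < r/(1-r)  <=>  b(1-r) < a r ; U: r/(1-r) < a/b  <=>  b r < a (1-r)
  lhs_L <- bE * (1 - r); rhs_L <- aE * r
  lhs_U <- bE * r; rhs_U <- aE * (1 - r)
  if (lhs_L == rhs_L || lhs_U == rhs_U) {
    case_id <- "boundary"
    desc <- "non-generic boundary (a phase-boundary equality holds exactly)"
  } else if (lhs_L < rhs_L && lhs_U < rhs_U) {
    case_id <- 1L; desc <- "consensus"
  } else if (lhs_L < rhs_L && lhs_U > rhs_U) {
    case_id <- 2L; desc <- "partisan polarization (red majority side)"
  } else if (lhs_L > rhs_L && lhs_U < rhs_U) {
    case_id <- 3L; desc <- "partisan polarization (blue majority side)"
  } else {
    case_id <- 4L; desc <- "nonpartisan polarization (unstable 50/50 split)"
  }
  structure(list(case_id = case_id, description = desc,
                 alpha_eff = aE, beta_eff = bE, r = r),
            class = "regime")
}

#' @export
print.regime <- function(x, ...) {
  cat(sprintf("regime: case %s — %s\n", x$case_id, x$description))
  invisible(x)
}

# analytic diagonal limit by case (delta = 0, theta_B(0) = theta_R(0) != 0.5)
diagonal_limit <- function(case_id, theta0_diag) {
  up <- theta0_diag > 0.5
  switch(as.character(case_id),
         "1" = if (up) c(1, 1) else c(0, 0),
         "2" = if (up) c(0, 1) else c(1, 0),
         "3" = if (up) c(1, 0) else c(0, 1),
         "4" = c(0.5, 0.5),
         NULL)
}

#' Limiting state of the mean-field dynamics
#'
#' For `delta = 0` and a group-independent off-centre initial state the
#' analytic case limit is returned directly (consensus at the initially
#' popular choice in case 1; in cases 2 and 3 the majority group keeps the
#' initially popular choice and the minority adopts the other; the centre
#' in case 4). Any other initial state is integrated with
#' [mf_integrate()] until convergence.
#'
#' @inheritParams mf_integrate
#' @return Named numeric vector `c(theta_B, theta_R)`.
#' @export
limiting_state <- function(theta0, cfg, horizon = 40) {
  theta0 <- as.numeric(theta0)
  if (cfg$params$delta == 0 && theta0[1L] == theta0[2L] &&
      theta0[1L] != 0.5) {
    reg <- classify_regime(cfg)
    lim <- diagonal_limit(reg$case_id, theta0[1L])
    if (!is.null(lim)) return(c(theta_B = lim[1L], theta_R = lim[2L]))
  }
  tr <- mf_integrate(theta0, cfg, horizon = horizon, sample_dt = horizon)
  attr(tr, "limit")
}

#' Is global consensus reachable from an initial state?
#'
#' With no inertia, consensus emerges from `theta0` if and only if
#' (i) the configuration is in the consensus regime (case 1), so a
#' consensus corner is a stable rest point, and (ii) both group drives at
#' `theta0` share the same nonzero sign, i.e. `theta0` lies in the convex
#' cone of states from which both groups move towards the same corner.
#' Within that cone each drive is monotone along the flow and keeps its
#' sign, so the segment to the corner stays inside the cone and the state
#' converges there.
#'
#' @inheritParams mf_integrate
#' @return A list of class `consensus_certificate`: `reachable` (logical),
#'   `corner` (the consensus corner, or `NA`), `case_id`, `drives` at
#'   `theta0`, and `reason` (which condition failed, if any).
#' @export
consensus_reachable <- function(theta0, cfg) {
  if (cfg$params$delta != 0)
    stop("consensus reachability analysis requires delta = 0")
  theta0 <- as.numeric(theta0)
  reg <- classify_regime(cfg)
  d <- mf_drives(theta0, cfg)
  out <- list(reachable = FALSE, corner = c(NA_real_, NA_real_),
              case_id = reg$case_id, drives = d, reason = "")
  class(out) <- "consensus_certificate"
  if (all(theta0 == 0.5)) {
    out$reason <- "fixed point: the centre state is stationary"
    return(out)
  }
  if (!identical(reg$case_id, 1L)) {
    out$reason <- sprintf(
      "condition (i) fails: configuration is case %s, consensus is not a stable rest point",
      reg$case_id)
    return(out)
  }
  s <- sign(d)
  if (s[1L] == 0 || s[2L] == 0 || s[1L] != s[2L]) {
    out$reason <- "condition (ii) fails: the group drives at theta0 do not share a nonzero sign"
    return(out)
  }
  out$reachable <- TRUE
  out$corner <- if (s[1L] > 0) c(1, 1) else c(0, 0)
  out$reason <- "case 1 and theta0 lies in the common-sign drive cone"
  out
}

#' @export
print.consensus_certificate <- function(x, ...) {
  cat(sprintf("consensus reachable: %s\n", x$reachable))
  cat(sprintf("  case: %s; drives at theta0: B = %.4g, R = %.4g\n",
              x$case_id, x$drives[1L], x$drives[2L]))
  cat(sprintf("  %s\n", x$reason))
  invisible(x)
}

#' Switching manifolds (tipping-point loci) in the state plane
#'
#' The four affine lines in the `(theta_B, theta_R)` unit square where a
#' group drive equals `+delta` or `-delta`. When a trajectory crosses one,
#' the corresponding group's trend changes (its rate switches branch).
#' At `delta = 0` the two lines of each group coincide and pass through
#' the centre `(0.5, 0.5)`.
#'
#' @param cfg An [mf_config()] object.
#' @return Data frame with columns `group` ("B"/"R"), `level` (`+delta` or
#'   `-delta`), and line coefficients `coef_B`, `coef_R`, `rhs` such that
#'   `coef_B * theta_B + coef_R * theta_R = rhs` on the manifold.
#' @export
switching_manifolds <- function(cfg) {
  co <- drive_coefs(cfg)
  delta <- cfg$params$delta
  out <- expand.grid(group = c("B", "R"), level = c(delta, -delta),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  gi <- match(out$group, c("B", "R"))
  out$coef_B <- co$cB[gi]
  out$coef_R <- co$cR[gi]
  out$rhs <- out$level - co$c0[gi]
  out
}
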