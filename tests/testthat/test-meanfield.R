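test_that("homophily rescaling of the effective parameters", {
  p <- model_params(0.8, 0.7, rho = 0.5)
  expect_equal(effective_params(mf_config(p, r = 0.5, mode = "sbm")),
               c(alpha = 0.4, beta = 0.35))
  expect_equal(effective_params(mf_config(p, r = 0.5)),
               c(alpha = 0.8, beta = 0.7))
  p7 <- model_params(0.8, 0.7, rho = 0.7)
  expect_equal(effective_params(mf_config(p7, r = 0.5, mode = "sbm")),
               c(alpha = 0.56, beta = 0.21))
  # rho -> 1 extinguishes out-group influence
  p99 <- model_params(0.8, 0.7, rho = 1 - 1e-9)
  expect_lt(effective_params(mf_config(p99, r = 0.5, mode = "sbm"))[["beta"]],
            1e-9)
})

test_that("group drives match hand arithmetic and the diagonal identity", {
  cfg <- mf_config(model_params(0.6, 0.5), r = 0.65)
  expect_equal(mf_drives(c(0.5, 0.5), cfg),
               c(drive_B = 0, drive_R = 0))
  d <- mf_drives(c(0.8, 0.8), cfg)
  expect_equal(d[["drive_B"]], 0.6 * 0.35 * 0.6 - 0.5 * 0.65 * 0.6)
  expect_equal(d[["drive_R"]], 0.6 * 0.65 * 0.6 - 0.5 * 0.35 * 0.6)
  # on the diagonal, sign(drive_B) = sign((2*th-1) * (a(1-r) - b r))
  set.seed(3)
  for (i in 1:50) {
    cfg2 <- rand_cfg()
    th <- runif(1)
    d2 <- mf_drives(c(th, th), cfg2)
    ep <- effective_params(cfg2)
    expect_equal(sign(d2[["drive_B"]]),
                 sign((2 * th - 1) *
                        (ep[["alpha"]] * (1 - cfg2$r) - ep[["beta"]] * cfg2$r)))
  }
})

test_that("rhs switches between growth, decay and frozen branches", {
  cfg <- mf_config(model_params(0.8, 0.4), r = 0.5)
  expect_equal(mf_rhs(c(0.8, 0.8), cfg),
               c(dtheta_B = 0.2, dtheta_R = 0.2))
  expect_equal(mf_rhs(c(1, 1), cfg), c(dtheta_B = 0, dtheta_R = 0))
  cfg_frozen <- mf_config(model_params(0.8, 0.4, delta = 0.5), r = 0.5)
  expect_equal(mf_rhs(c(0.6, 0.6), cfg_frozen),
               c(dtheta_B = 0, dtheta_R = 0))
})

test_that("event-driven integration reproduces closed-form trajectories", {
  # case-1 parameters: both components follow 1 - 0.2 exp(-t)
  cfg <- mf_config(model_params(0.8, 0.4), r = 0.5)
  tr <- mf_integrate(c(0.8, 0.8), cfg, horizon = 10, sample_dt = 0.1)
  expect_equal(tr$theta_B, 1 - 0.2 * exp(-tr$t), tolerance = 1e-12)
  expect_equal(tr$theta_R, 1 - 0.2 * exp(-tr$t), tolerance = 1e-12)
  expect_equal(unname(attr(tr, "limit")), c(1, 1))
  # case-4 parameters: theta' = -theta gives 0.8 exp(-t), frozen once the
  # diagonal trajectory reaches the centre at t = log(1.6)
  cfg4 <- mf_config(model_params(0.3, 0.9), r = 0.5)
  tr4 <- mf_integrate(c(0.8, 0.8), cfg4, horizon = 10, sample_dt = 0.1)
  expect_equal(tr4$theta_B, pmax(0.5, 0.8 * exp(-tr4$t)), tolerance = 1e-9)
  expect_equal(tr4$theta_R, tr4$theta_B)
  # both groups freeze exactly when the diagonal hits the centre
  ev4 <- attr(tr4, "events")
  expect_setequal(ev4$group, c("B", "R"))
  expect_equal(ev4$t, rep(log(1.6), 2L), tolerance = 1e-9)
  expect_true(all(ev4$to_region == 0L))
  # the centre is an exact fixed point
  trc <- mf_integrate(c(0.5, 0.5), cfg)
  expect_true(attr(trc, "converged"))
  expect_equal(unname(attr(trc, "theta_final")), c(0.5, 0.5))
  expect_equal(nrow(trc), 1L)
})

test_that("event integration matches a fine fixed-step Euler oracle", {
  set.seed(7)
  n_cfg <- 100
  aa <- runif(n_cfg, 0.05, 1); bb <- runif(n_cfg, 0.05, 1)
  rr <- runif(n_cfg, 0.1, 0.9)
  dd <- ifelse(runif(n_cfg) < 0.5, 0, runif(n_cfg, 0, 0.3))
  t0B <- runif(n_cfg); t0R <- runif(n_cfg)
  horizon <- 6; dt <- 1e-4
  eu <- euler_batch(t0B, t0R, aa, bb, rr, dd, horizon, dt)
  worst <- 0
  for (i in seq_len(n_cfg)) {
    cfg <- mf_config(model_params(aa[i], bb[i], dd[i]), r = rr[i])
    tr <- mf_integrate(c(t0B[i], t0R[i]), cfg, horizon = horizon,
                       sample_dt = 0.1)
    at <- vapply(eu$t, function(tt) {
      j <- which.min(abs(tr$t - tt)); c(tr$theta_B[j], tr$theta_R[j])
    }, numeric(2))
    worst <- max(worst, abs(at[1L, ] - eu$B[, i]), abs(at[2L, ] - eu$R[, i]))
  }
  expect_lt(worst, 1e-3)
})

test_that("regime classification follows the phase-boundary inequalities", {
  expect_identical(
    classify_regime(mf_config(model_params(0.8, 0.4), r = 0.5))$case_id, 1L)
  # the homophily-flip configuration: consensus at rho = 0.7,
  # partisan (red majority) at rho = 0.5
  expect_identical(
    classify_regime(mf_config(model_params(0.8, 0.7, rho = 0.7), r = 0.65,
                              mode = "sbm"))$case_id, 1L)
  expect_identical(
    classify_regime(mf_config(model_params(0.8, 0.7, rho = 0.5), r = 0.65,
                              mode = "sbm"))$case_id, 2L)
  # negligible out-group hate is always consensus
  expect_identical(
    classify_regime(mf_config(model_params(0.6, 0), r = 0.8))$case_id, 1L)
  # equalities yield the non-generic boundary case
  expect_identical(
    classify_regime(mf_config(model_params(0.5, 0.5), r = 0.5))$case_id,
    "boundary")
  expect_error(classify_regime(mf_config(model_params(0, 0), r = 0.5)),
               "zero")
})

test_that("diagonal limits match the case predictions on random draws", {
  set.seed(13)
  for (i in 1:500) {
    cfg <- rand_cfg(boundary_gap = 1e-3)
    th0 <- sample(c(0.2, 0.8), 1L)
    pred <- limiting_state(c(th0, th0), cfg)
    got <- attr(mf_integrate(c(th0, th0), cfg, horizon = 40,
                             sample_dt = 40), "theta_final")
    expect_equal(got, pred, tolerance = 1e-6)
  }
})

test_that("case-2 integration gives the red majority the popular choice", {
  cfg <- mf_config(model_params(0.6, 0.5), r = 0.65)
  expect_identical(classify_regime(cfg)$case_id, 2L)
  lim <- attr(mf_integrate(c(0.8, 0.8), cfg, sample_dt = 40), "theta_final")
  expect_equal(unname(lim), c(0, 1), tolerance = 1e-6)
  expect_equal(unname(limiting_state(c(0.8, 0.8), cfg)), c(0, 1))
  expect_equal(unname(limiting_state(c(0.2, 0.2), cfg)), c(1, 0))
})

test_that("unscaled red-drive variant differs and breaks the diagonal boundary", {
  p <- model_params(0.6, 0.5)
  sym <- mf_config(p, r = 0.65)
  uns <- mf_config(p, r = 0.65, red_drive = "unscaled")
  d_sym <- mf_drives(c(0.8, 0.8), sym)
  d_uns <- mf_drives(c(0.8, 0.8), uns)
  expect_equal(d_uns[["drive_B"]], d_sym[["drive_B"]])
  expect_equal(d_uns[["drive_R"]], 0.6 * 0.6 - 0.5 * 0.35 * 0.6)
  # at r = 0.5 the symmetric red drive mirrors the blue one; unscaled does
  # not
  sym5 <- mf_config(p, r = 0.5)
  uns5 <- mf_config(p, r = 0.5, red_drive = "unscaled")
  expect_equal(mf_drives(c(0.7, 0.7), sym5)[["drive_R"]],
               mf_drives(c(0.7, 0.7), sym5)[["drive_B"]])
  expect_gt(mf_drives(c(0.7, 0.7), uns5)[["drive_R"]],
            mf_drives(c(0.7, 0.7), uns5)[["drive_B"]])
})

test_that("case-4 centre is unstable: a small perturbation polarizes", {
  cfg <- mf_config(model_params(0.3, 0.9), r = 0.5)
  tr <- mf_integrate(c(0.5 + 1e-3, 0.5), cfg, horizon = 40, sample_dt = 40)
  th <- attr(tr, "theta_final")
  expect_gte(abs(th[["theta_B"]] - th[["theta_R"]]), 0.99)
  trc <- mf_integrate(c(0.5, 0.5), cfg)
  expect_equal(unname(attr(trc, "theta_final")), c(0.5, 0.5))
})

test_that("group-swap symmetry commutes with integration exactly", {
  set.seed(17)
  for (i in 1:20) {
    a <- runif(1, 0.05, 1); b <- runif(1, 0.05, 1)
    # dyadic r so that the mirrored group size 1 - r is exact in floating
    # point and the two integrations perform identical arithmetic
    r <- sample(seq(0.125, 0.875, by = 1 / 64), 1L)
    d <- sample(c(0, 0.1), 1L)
    th0 <- runif(2)
    tr1 <- mf_integrate(th0, mf_config(model_params(a, b, d), r = r),
                        horizon = 15, sample_dt = 0.5)
    tr2 <- mf_integrate(rev(th0), mf_config(model_params(a, b, d), r = 1 - r),
                        horizon = 15, sample_dt = 0.5)
    expect_identical(tr1$theta_B, tr2$theta_R)
    expect_identical(tr1$theta_R, tr2$theta_B)
    expect_identical(tr1$t, tr2$t)
  }
})

test_that("consensus checker agrees with integration on a coarse grid", {
  set.seed(23)
  n_checked <- 0L
  for (k in 1:5) {
    repeat {
      cfg <- rand_cfg(boundary_gap = 1e-3)
      if (identical(classify_regime(cfg)$case_id, 1L)) break
    }
    for (tB in seq(0.05, 0.95, by = 0.15)) {
      for (tR in seq(0.05, 0.95, by = 0.15)) {
        d <- mf_drives(c(tB, tR), cfg)
        if (any(abs(d) < 1e-3)) next
        chk <- consensus_reachable(c(tB, tR), cfg)
        lim <- attr(mf_integrate(c(tB, tR), cfg, horizon = 60,
                                 sample_dt = 60), "theta_final")
        oracle <- isTRUE(all.equal(unname(lim), c(0, 0), tolerance = 1e-6)) ||
          isTRUE(all.equal(unname(lim), c(1, 1), tolerance = 1e-6))
        expect_identical(chk$reachable, oracle)
        if (chk$reachable)
          expect_equal(unname(lim), chk$corner, tolerance = 1e-6)
        n_checked <- n_checked + 1L
      }
    }
  }
  expect_gt(n_checked, 100L)
})

test_that("consensus checker certificates name the failing condition", {
  cfg2 <- mf_config(model_params(0.6, 0.5), r = 0.65)
  chk <- consensus_reachable(c(0.9, 0.6), cfg2)
  expect_false(chk$reachable)
  expect_match(chk$reason, "condition \\(i\\)")
  cfg1 <- mf_config(model_params(0.8, 0.4), r = 0.5)
  expect_true(consensus_reachable(c(0.8, 0.8), cfg1)$reachable)
  chk_c <- consensus_reachable(c(0.5, 0.5), cfg1)
  expect_false(chk_c$reachable)
  expect_match(chk_c$reason, "fixed point")
  expect_error(consensus_reachable(c(0.8, 0.8),
                                   mf_config(model_params(0.8, 0.4, 0.1),
                                             r = 0.5)),
               "delta")
})

test_that("switching manifolds pass through the centre and have the predicted slope", {
  cfg <- mf_config(model_params(0.7, 0.5), r = 0.6)
  sm <- switching_manifolds(cfg)
  bl <- sm[sm$group == "B" & sm$level == 0, ][1L, ]
  # delta = 0: the blue manifold contains (0.5, 0.5)
  expect_equal(bl$coef_B * 0.5 + bl$coef_R * 0.5, bl$rhs)
  # slope dthetaR/dthetaB = a(1-r) / (b r)
  expect_equal(-bl$coef_B / bl$coef_R, 0.7 * 0.4 / (0.5 * 0.6))
  # a trajectory's recorded reversal sits on the crossed manifold
  pr <- list(alpha = 0.5, beta = 0.7, r = 0.65, theta0 = c(0.9, 0.7))
  cfg2 <- mf_config(model_params(pr$alpha, pr$beta), r = pr$r)
  tr <- mf_integrate(pr$theta0, cfg2, sample_dt = 0.01)
  rev_ev <- detect_reversal(tr)
  expect_identical(rev_ev$group, "B")
  i <- which.min(abs(tr$t - rev_ev$t[1L]))
  smb <- switching_manifolds(cfg2)
  smb <- smb[smb$group == "B", ][1L, ]
  expect_equal(smb$coef_B * tr$theta_B[i] + smb$coef_R * tr$theta_R[i],
               smb$rhs, tolerance = 1e-9)
})

test_that("trajectories stay inside the unit square", {
  set.seed(29)
  for (i in 1:50) {
    cfg <- rand_cfg(delta = sample(c(0, 0.2), 1L))
    tr <- mf_integrate(runif(2), cfg, horizon = 20, sample_dt = 0.5)
    expect_true(all(tr$theta_B >= 0 & tr$theta_B <= 1))
    expect_true(all(tr$theta_R >= 0 & tr$theta_R <= 1))
    expect_true(all(diff(tr$t) > 0))
  }
})
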