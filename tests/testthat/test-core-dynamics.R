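test_that("neighbourhood fractions match hand counts and sum to one", {
  # star: centre and 4 same-group leaves all at choice 1
  star <- labeled_graph(5, cbind(1L, 2:5), group = rep(0L, 5))
  expect_equal(neighbor_stats(star, c(0L, 1L, 1L, 1L, 1L), 1L),
               c(in0 = 0, in1 = 1, out0 = 0, out1 = 0))
  # degree 4: in-group 2 choose 1, 1 chooses 0; out-group 1 chooses 1
  g <- labeled_graph(5, cbind(1L, 2:5),
                     group = c(0L, 0L, 0L, 0L, 1L))
  st <- neighbor_stats(g, c(0L, 1L, 1L, 0L, 1L), 1L)
  expect_equal(st, c(in0 = 0.25, in1 = 0.5, out0 = 0, out1 = 0.25))
  set.seed(11)
  for (i in 1:20) {
    gr <- rand_graph()
    ch <- rbinom(gr$n, 1L, 0.5)
    for (v in seq_len(gr$n))
      expect_equal(sum(neighbor_stats(gr, ch, v)), 1)
  }
})

test_that("complete-graph neighbour fractions equal the group-level formulas with self excluded", {
  set.seed(5)
  n <- 40
  g <- complete_graph(n)
  g <- set_group(g, assign_random(g, 0.3))
  ch <- init_choices(g$group, c(0.6, 0.4))
  th <- group_state(g, ch)
  nB <- sum(g$group == 0L); nR <- n - nB
  for (v in c(1L, 7L, 25L)) {
    st <- neighbor_stats(g, ch, v)
    own <- if (g$group[v] == 0L) "theta_B" else "theta_R"
    oth <- setdiff(c("theta_B", "theta_R"), own)
    n_own <- if (g$group[v] == 0L) nB else nR
    n_oth <- n - n_own
    expect_equal(st[["in1"]], (th[[own]] * n_own - ch[v]) / (n - 1))
    expect_equal(st[["out1"]], th[[oth]] * n_oth / (n - 1))
    # population approximation theta * group share, up to the excluded self
    expect_equal(st[["out1"]], th[[oth]] * n_oth / n, tolerance = 2 / n)
  }
})

test_that("drive arithmetic follows the love/hate weighting", {
  p <- model_params(0.8, 0.7)
  expect_equal(drive(c(in0 = 0.2, in1 = 0.4, out0 = 0.1, out1 = 0.3), p),
               0.8 * 0.2 - 0.7 * 0.2)
  # beta = 0 kills a purely out-group neighbourhood
  expect_equal(drive(c(in0 = 0, in1 = 0, out0 = 0.5, out1 = 0.5),
                     model_params(0.9, 0)), 0)
  # symmetric neighbourhood cancels
  expect_equal(drive(c(in0 = 0.3, in1 = 0.3, out0 = 0.2, out1 = 0.2), p), 0)
})

test_that("relabelling symmetries hold exactly on random graphs", {
  set.seed(21)
  for (i in 1:25) {
    g <- rand_graph()
    ch <- rbinom(g$n, 1L, 0.5)
    p <- model_params(runif(1), runif(1))
    v <- sample.int(g$n, 1L)
    # complementing all choices negates the drive
    expect_identical(node_drive(g, 1L - ch, v, p), -node_drive(g, ch, v, p))
    # a global label swap leaves the same-group relation (and drive) alone
    g_all <- set_group(g, 1L - g$group)
    st <- neighbor_stats(g, ch, v)
    expect_identical(neighbor_stats(g_all, ch, v), st)
    expect_identical(node_drive(g_all, ch, v, p), node_drive(g, ch, v, p))
    # flipping only the focal node's label swaps its in/out statistics,
    # and swapping the weights along with it negates the drive
    g_v <- set_group(g, replace(g$group, v, 1L - g$group[v]))
    sts <- neighbor_stats(g_v, ch, v)
    expect_identical(unname(sts[c("out0", "out1", "in0", "in1")]),
                     unname(st[c("in0", "in1", "out0", "out1")]))
    p_swapped <- model_params(p$beta, p$alpha)
    expect_equal(node_drive(g_v, ch, v, p_swapped),
                 -node_drive(g, ch, v, p))
  }
})

test_that("threshold update keeps the current choice at exact boundaries", {
  # degree-10 node with fractions (in0, in1, out0, out1) = (.2, .4, .1, .3):
  # drive = 0.8*0.2 - 0.7*0.2 = 0.02
  g <- labeled_graph(11, cbind(1L, 2:11),
                     group = c(0L, rep(0L, 6), rep(1L, 4)))
  ch <- c(0L, 1L, 1L, 1L, 1L, 0L, 0L, 1L, 1L, 1L, 0L)
  expect_equal(node_drive(g, ch, 1L, model_params(0.8, 0.7)), 0.02)
  expect_identical(update_choice(g, ch, 1L, model_params(0.8, 0.7)), 1L)
  # inertia: |drive| <= delta keeps the current choice
  expect_identical(update_choice(g, ch, 1L, model_params(0.8, 0.7, 0.05)),
                   0L)
  # all in-group neighbours at 0, alpha > delta: node abandons choice 1
  star <- labeled_graph(4, cbind(1L, 2:4), group = rep(0L, 4))
  expect_identical(update_choice(star, c(1L, 0L, 0L, 0L),
                                 1L, model_params(0.6, 0.2, 0.1)), 0L)
  # drive exactly delta: strict inequality keeps the current choice
  expect_identical(update_choice(star, c(0L, 1L, 1L, 1L), 1L,
                                 model_params(0.5, 0, 0.5)), 0L)
  expect_identical(update_choice(star, c(0L, 1L, 1L, 1L), 1L,
                                 model_params(0.5, 0, 0.49)), 1L)
})

test_that("update rule agrees with a literal brute-force oracle", {
  set.seed(31)
  checked <- 0L
  while (checked < 1000L) {
    g <- rand_graph(n = sample(6:15, 1L))
    ch <- rbinom(g$n, 1L, runif(1, 0.2, 0.8))
    p <- model_params(runif(1), runif(1), sample(c(0, runif(1, 0, 0.4)), 1L))
    for (v in sample.int(g$n, min(5L, g$n))) {
      expect_identical(update_choice(g, ch, v, p), brute_update(g, ch, v, p))
      checked <- checked + 1L
    }
  }
})

test_that("group state counts per-group adoption and respects symmetry", {
  g <- labeled_graph(15, cbind(1:14, 2:15),
                     group = c(rep(0L, 10), rep(1L, 5)))
  ch <- c(rep(1L, 4), rep(0L, 6), rep(1L, 5))
  expect_equal(group_state(g, ch), c(theta_B = 0.4, theta_R = 1.0))
  expect_equal(group_state(g, rep(1L, 15)), c(theta_B = 1, theta_R = 1))
  expect_equal(group_state(g, 1L - ch), 1 - group_state(g, ch))
  g1 <- set_group(g, rep(0L, 15))
  expect_error(group_state(g1, ch), "nonempty")
})

test_that("isolated nodes are rejected with a clear error", {
  g <- labeled_graph(4, rbind(c(1L, 2L), c(2L, 3L)),
                     group = c(0L, 0L, 1L, 1L))
  ch <- c(0L, 1L, 1L, 0L)
  expect_error(neighbor_stats(g, ch, 4L), "isolated")
  expect_error(abm_run(g, model_params(0.5, 0.5), choices = ch, seed = 1),
               "isolated")
  expect_warning(
    abm_run(g, model_params(0.5, 0.5), choices = ch, seed = 1,
            max_steps = 20, tolerate_isolates = TRUE),
    "skipping")
})

test_that("parameter validation enforces the documented domains", {
  expect_error(model_params(1.2, 0.5), "alpha")
  expect_error(model_params(0.5, -0.1), "beta")
  expect_error(model_params(0.5, 0.5, rho = 1), "rho")
  expect_error(labeled_graph(3, rbind(c(1L, 1L))), "self loops")
  expect_error(labeled_graph(3, rbind(c(1L, 4L))), "node ids")
  # reversed duplicates collapse to one edge
  g <- labeled_graph(3, rbind(c(1L, 2L), c(2L, 1L)))
  expect_equal(n_edges(g), 1)
})
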