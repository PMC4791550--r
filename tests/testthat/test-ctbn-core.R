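test_that("point observations become hold-forward trajectories", {
  obs <- tibble::tibble(time_h = c(0, 2, 5), x = c(0L, 0L, 1L))
  traj <- trajectory_from_observations(obs)
  st <- sufficient_statistics(traj, "x", n_states = 2)
  expect_equal(st$T[, 1], c(5, 0))          # final observation has zero dwell
  expect_equal(st$M[1, 2, 1], 1L)
  expect_equal(sum(st$M), 1L)
  # constant observations: full-horizon dwell, no transitions
  traj_c <- trajectory_from_observations(tibble::tibble(time_h = c(0, 3, 7), x = 1L))
  st_c <- sufficient_statistics(traj_c, "x", n_states = 2)
  expect_equal(st_c$T[, 1], c(0, 7))
  expect_equal(sum(st_c$M), 0L)
  expect_error(trajectory_from_observations(tibble::tibble(time_h = c(2, 1), x = 0L)),
               "increasing")
})

test_that("sufficient statistics stratify by the pre-transition parent state", {
  # x flips 0 -> 1 at t = 4 while p = 1 since t = 3
  traj <- manual_trajectory(c(0, 3, 4), c(3, 4, 5),
                            tibble::tibble(x = c(0L, 0L, 1L), p = c(0L, 1L, 1L)))
  st <- sufficient_statistics(traj, "x", "p", n_states = 2)
  expect_equal(st$T[1, 1], 3)     # x = 0 under p = 0
  expect_equal(st$T[1, 2], 1)     # x = 0 under p = 1
  expect_equal(st$T[2, 2], 1)     # x = 1 under p = 1
  expect_equal(st$M[1, 2, 2], 1L) # the flip is attributed to p = 1
  expect_equal(sum(st$M), 1L)
  # unknown variable errors
  expect_error(sufficient_statistics(traj, "zz"), "absent")
})

test_that("pooled statistics over replicates are additive", {
  model <- generate_model(generator_config(n_genes = 3, seed = 5))
  t1 <- sample_trajectory(model, 30, seed = 1)
  t2 <- sample_trajectory(model, 30, seed = 2)
  t2$trajectory_id <- 2L
  pooled <- ctbnflow:::new_trajectory(dplyr::bind_rows(t1, t2), model$variables)
  for (v in model$variables) {
    sp <- sufficient_statistics(pooled, v, setdiff(model$variables, v)[1], n_states = 3)
    s1 <- sufficient_statistics(t1, v, setdiff(model$variables, v)[1], n_states = 3)
    s2 <- sufficient_statistics(t2, v, setdiff(model$variables, v)[1], n_states = 3)
    expect_equal(sp$T, s1$T + s2$T)
    expect_equal(sp$M, s1$M + s2$M)
  }
})

test_that("statistics conserve total dwell and jump counts", {
  model <- generate_model(generator_config(n_genes = 4, seed = 6))
  traj <- sample_trajectories(model, 5, horizon = 40, seed = 3)
  n_jumps <- nrow(traj) - 5L  # one initial segment per trajectory
  total_m <- 0L
  for (v in model$variables) {
    st <- sufficient_statistics(traj, v, n_states = 3)
    expect_equal(sum(st$T), 5 * 40, tolerance = 1e-9)
    total_m <- total_m + sum(st$M)
  }
  expect_equal(total_m, n_jumps)
})

test_that("the family score is zero on no data and decreases in dwell time", {
  empty <- structure(list(T = matrix(0, 3, 2), M = array(0L, c(3, 3, 2)),
                          variable = "x", parents = "p", cards = c(3, 2)),
                     class = "ctbn_suffstats")
  expect_identical(family_log_score(empty), 0)
  st <- structure(list(T = matrix(c(2, 3), 2, 1), M = array(0L, c(2, 2, 1)),
                       variable = "x", parents = character(), cards = 2),
                  class = "ctbn_suffstats")
  st$M[1, 2, 1] <- 1L
  s0 <- family_log_score(st)
  st2 <- st; st2$T[1, 1] <- 4
  expect_lt(family_log_score(st2), s0)
  expect_error(family_log_score(st, learn_config(tau = -1)), "tau")
})

test_that("the closed-form score matches Monte-Carlo prior integration", {
  set.seed(8)
  zs <- vapply(1:5, function(i) {
    st <- random_small_stats()
    closed <- family_log_score(st, learn_config(alpha = 0.01, tau = 5))
    mc <- mc_family_score(st$T, st$M, 0.01, 5, n_draws = 2e5, seed = 800 + i)
    (exp(closed - mc$shift) - mc$mean_w) / mc$se_w
  }, numeric(1))
  expect_true(all(abs(zs) < 3))
})

test_that("the network score decomposes over families", {
  model <- generate_model(generator_config(n_genes = 4, seed = 7))
  traj <- sample_trajectories(model, 4, horizon = 30, seed = 4)
  parent_sets <- list(g001 = "g002", g002 = character(),
                      g003 = c("g001", "g004"), g004 = "g003")
  total <- network_log_score(traj, parent_sets, n_states = 3)
  by_family <- sum(vapply(names(parent_sets), function(v) {
    family_log_score(sufficient_statistics(traj, v, parent_sets[[v]], n_states = 3))
  }, numeric(1)))
  expect_equal(total, by_family, tolerance = 1e-10)
  # adding a parent changes only that family's term
  ps2 <- parent_sets; ps2$g002 <- "g001"
  delta <- network_log_score(traj, ps2, n_states = 3) - total
  fam_delta <- family_log_score(sufficient_statistics(traj, "g002", "g001", n_states = 3)) -
    family_log_score(sufficient_statistics(traj, "g002", n_states = 3))
  expect_equal(delta, fam_delta, tolerance = 1e-10)
  expect_error(network_log_score(traj, parent_sets, learn_config(max_parents = 1),
                                 n_states = 3), "max_parents")
})

test_that("greedy search finds a strongly modulated parent and nothing else", {
  # x2's leave rates depend strongly on x1; x1 is autonomous
  q1 <- matrix(c(-0.3, 0.3, 0.3, -0.3), 2, 2, byrow = TRUE)
  cim_slow <- matrix(c(-0.05, 0.05, 0.05, -0.05), 2, 2, byrow = TRUE)
  cim_fast <- matrix(c(-1.5, 1.5, 1.5, -1.5), 2, 2, byrow = TRUE)
  model <- ctbn_model(c("x1", "x2"), 2L, parents = list(x2 = "x1"),
                      cims = list(x1 = list(q1), x2 = list(cim_slow, cim_fast)))
  traj <- sample_trajectories(model, 200, horizon = 72, seed = 10)
  fit <- greedy_structure_search(traj, learn_config(max_parents = 2), n_states = 2)
  expect_identical(fit$parents$x2, "x1")
  expect_identical(fit$parents$x1, character())
  ex <- exhaustive_structure_search(traj, learn_config(max_parents = 2), n_states = 2)
  expect_identical(ex$parents, fit$parents)
  # max_parents = 0 forces the empty graph
  fit0 <- greedy_structure_search(traj, learn_config(max_parents = 0), n_states = 2)
  expect_true(all(lengths(fit0$parents) == 0))
})

test_that("independent variables yield an empty learned graph", {
  cim <- function(q) matrix(c(-q, q, q, -q), 2, 2, byrow = TRUE)
  model <- ctbn_model(c("a", "b", "c"), 2L,
                      cims = list(a = list(cim(0.2)), b = list(cim(0.4)),
                                  c = list(cim(0.3))))
  traj <- sample_trajectories(model, 150, horizon = 60, seed = 12)
  fit <- greedy_structure_search(traj, learn_config(max_parents = 2), n_states = 2)
  expect_true(all(lengths(fit$parents) == 0))
  ex <- exhaustive_structure_search(traj, learn_config(max_parents = 2), n_states = 2)
  expect_true(all(lengths(ex$parents) == 0))
})

test_that("greedy never beats the exhaustive optimum and usually attains it", {
  matches <- 0L
  for (i in 1:10) {
    cfg <- generator_config(n_genes = 4, n_states = 2, level_map = c(-2, 2),
                            max_true_parents = 2, seed = 100 + i)
    model <- generate_model(cfg)
    traj <- sample_trajectories(model, 5, horizon = 30, seed = 200 + i)
    lc <- learn_config(max_parents = 2)
    g <- greedy_structure_search(traj, lc, n_states = 2)
    e <- exhaustive_structure_search(traj, lc, n_states = 2)
    expect_lte(g$log_score, e$log_score + 1e-9)
    if (identical(g$parents, e$parents)) matches <- matches + 1L
  }
  expect_gte(matches, 7L)
  # the exhaustive oracle refuses oversized search spaces with an estimate
  model <- generate_model(generator_config(n_genes = 6, seed = 1))
  traj <- sample_trajectories(model, 2, horizon = 10, seed = 1)
  expect_error(
    exhaustive_structure_search(traj, learn_config(max_parents = 2,
                                                   exhaustive_cap = 10),
                                n_states = 3),
    "candidate families")
})

test_that("posterior parameter estimates follow the closed form and the data limit", {
  lc <- learn_config(alpha = 0.01, tau = 5)
  empty <- structure(list(T = matrix(0, 2, 1), M = array(0L, c(2, 2, 1)),
                          variable = "x", parents = character(), cards = 2),
                     class = "ctbn_suffstats")
  est0 <- estimate_parameters(empty, lc)
  expect_equal(est0$q_hat[1, 1], 1.01 / 5)
  # theta rows sum to 1 and CIM rows to 0 for arbitrary stats
  set.seed(20)
  st <- random_small_stats()
  est <- estimate_parameters(st, lc)
  k <- nrow(st$T)
  for (u in seq_len(ncol(st$T))) {
    expect_equal(rowSums(est$theta_hat[, , u, drop = FALSE][, , 1]), rep(1, k))
    expect_equal(rowSums(est$cims[[u]]), rep(0, k), tolerance = 1e-12)
  }
  # with abundant data q_hat approaches the empirical rate M/T
  q_true <- c(0.3, 0.7)
  cim <- matrix(c(-q_true[1], q_true[1], q_true[2], -q_true[2]), 2, 2, byrow = TRUE)
  model <- ctbn_model("x", 2L, cims = list(x = list(cim)))
  traj <- sample_trajectory(model, 6000, seed = 30)
  st_big <- sufficient_statistics(traj, "x", n_states = 2)
  expect_gte(min(apply(st_big$M, c(1, 3), sum)), 500)
  est_big <- estimate_parameters(st_big, lc)
  expect_lt(max(abs(est_big$q_hat[, 1] - q_true) / q_true), 0.1)
})
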