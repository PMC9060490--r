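test_that("transition estimation matches enumeration on fixtures", {
  # nobody switches -> identity matrix
  p <- panel_from_trajectories(purrr::map(0:4, ~ rep(.x, 3)))
  tm <- estimate_transitions(p, "voluntary", 1, 2)
  expect_equal(unname(tm$P), diag(5))

  # 10 opposed in the collapsed chain, 4 stay opposed
  traj <- c(purrr::map(1:4, ~ c(0, 1, 1)), purrr::map(1:6, ~ c(0, 4, 4)))
  tm2 <- estimate_transitions(panel_from_trajectories(traj), "voluntary",
                              1, 2, state_space = "collapsed3")
  expect_equal(tm2$P["opposed", "opposed"], 0.4)
  expect_equal(tm2$P["opposed", "willing"], 0.6)
  expect_equal(sum(tm2$counts["opposed", ]), 10)
})

test_that("empty origin states are flagged and handled per rule", {
  p <- panel_from_trajectories(list(c(0, 1, 1), c(4, 4, 4)))
  tm <- estimate_transitions(p, "voluntary", 1, 2)
  expect_setequal(tm$empty_states, c("1", "2", "3"))
  expect_equal(tm$P["2", "2"], 1)  # self-loop default
  tu <- estimate_transitions(p, "voluntary", 1, 2, empty = "uniform")
  expect_equal(unname(tu$P["2", ]), rep(0.2, 5))
  # Laplace smoothing removes the emptiness
  ts <- estimate_transitions(p, "voluntary", 1, 2, alpha = 0.5)
  expect_length(ts$empty_states, 0)
  expect_equal(rowSums(ts$P), rep(1, 5), ignore_attr = TRUE)
})

test_that("stationary distribution solves pi P = pi with cross-checks", {
  # doubly stochastic -> uniform by symmetry
  P <- matrix(c(0.5, 0.3, 0.2,
                0.2, 0.5, 0.3,
                0.3, 0.2, 0.5), 3, 3, byrow = TRUE)
  sd3 <- stationary_distribution(P)
  expect_equal(unname(sd3$pi), rep(1 / 3, 3), tolerance = 1e-12)

  # 2-state closed form: pi = (q/(p+q), p/(p+q))
  for (pq in list(c(0.3, 0.1), c(0.05, 0.6), c(0.9, 0.9))) {
    p <- pq[1]; q <- pq[2]
    P2 <- matrix(c(1 - p, p, q, 1 - q), 2, 2, byrow = TRUE)
    s <- stationary_distribution(P2)
    expect_equal(unname(s$pi), c(q, p) / (p + q), tolerance = 1e-12)
    expect_lt(s$residual, 1e-10)
    expect_lt(s$power_residual, 1e-8)
  }

  # identity chain: every distribution is stationary -> diagnostic error
  expect_error(stationary_distribution(diag(3)), "reducible.*closed classes")
  # two absorbing blocks, classes named
  Pr <- matrix(c(1, 0, 0, 0,
                 0.5, 0.5, 0, 0,
                 0, 0, 0.5, 0.5,
                 0, 0, 0.2, 0.8), 4, 4, byrow = TRUE)
  expect_error(stationary_distribution(Pr), "closed classes.*and")
})

test_that("projection iterates the chain and converges to stationarity", {
  P <- default_transition_matrix(0.5, 0.6)
  init <- c(1, 0, 0, 0, 0)
  pr0 <- project_chain(init, P, 0)
  expect_equal(unname(unlist(pr0[1, -1])), init)

  st <- stationary_distribution(P)
  prs <- project_chain(st$pi, P, 5)
  for (k in 1:6) {
    expect_equal(unname(unlist(prs[k, -1])), unname(st$pi), tolerance = 1e-12)
  }

  prc <- project_chain(init, P, 200)
  expect_lt(max(abs(unlist(prc[201, -1]) - st$pi)), 1e-8)
  # probability mass preserved at every step
  expect_equal(rowSums(prc[, -1]), rep(1, 201), tolerance = 1e-12)
  expect_error(project_chain(c(0.5, 0.5), P, 3), "states")
})

test_that("estimated transitions recover the generating matrix", {
  P <- default_transition_matrix(0.6, 0.7)
  sim <- simulate_panel(sim_config(
    n_respondents = 8000, transitions_voluntary = P,
    uptake_probability = 0, once_probability = 0, seed = 5))
  tm <- estimate_transitions(sim$panel, "voluntary", 1, 2)
  n_row <- rowSums(tm$counts)
  for (i in 1:5) for (j in 1:5) {
    expect_lt(abs(tm$P[i, j] - P[i, j]),
              mn_joint_band(P[i, j], n_row[i], 25))
  }
})

test_that("stationary opposed share falls as escape from opposition rises", {
  base <- matrix(c(0.6, 0.2, 0.2,
                   0.2, 0.5, 0.3,
                   0.1, 0.2, 0.7), 3, 3, byrow = TRUE,
                 dimnames = list(from = c("opposed", "undecided", "willing"),
                                 to = c("opposed", "undecided", "willing")))
  shares <- vapply(seq(0, 0.5, by = 0.05), function(extra) {
    P <- base
    P[1, ] <- c(0.6 - extra, 0.2, 0.2 + extra)  # shift opposed -> willing
    stationary_distribution(P)$pi[["opposed"]]
  }, numeric(1))
  expect_true(all(diff(shares) <= 1e-12))
})

test_that("bootstrap intervals bracket the point estimate", {
  sim <- simulate_panel(sim_config(n_respondents = 400,
                                   uptake_probability = 0, seed = 9))
  bs <- bootstrap_stationary(sim$panel, "voluntary", 1, 2,
                             n_boot = 30, seed = 1)
  expect_true(all(bs$lower <= bs$estimate + 1e-12))
  expect_true(all(bs$estimate <= bs$upper + 1e-12))
})
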