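test_that("the same seed reproduces the panel exactly", {
  cfg <- sim_config(n_respondents = 120, misreport_rate = 0.2, seed = 77)
  a <- simulate_panel(cfg)
  b <- simulate_panel(cfg)
  expect_identical(a$panel, b$panel)
  expect_identical(a$truth, b$truth)
  # a different seed changes the draw
  c <- simulate_panel(sim_config(n_respondents = 120, misreport_rate = 0.2,
                                 seed = 78))
  expect_false(identical(a$panel, c$panel))
})

test_that("config validation rejects malformed probability inputs", {
  expect_error(sim_config(initial_voluntary = c(0.5, 0.5, 0, 0, 0.1)),
               "summing to 1")
  bad <- default_transition_matrix(); bad[1, 1] <- bad[1, 1] + 0.1
  expect_error(sim_config(transitions_voluntary = bad), "row-stochastic")
  expect_error(sim_config(misreport_rate = 1.2), "\\[0, 1\\]")
})

test_that("full-noise observations are uniform over the five levels", {
  sim <- simulate_panel(sim_config(n_respondents = 4000, misreport_rate = 1,
                                   uptake_probability = 0,
                                   once_probability = 0, seed = 14))
  obs <- table(factor(sim$panel$vol_likert, levels = 0:4))
  n_obs <- sum(obs)
  for (k in 1:5) {
    expect_lt(abs(obs[k] / n_obs - 0.2), mn_3se(0.2, n_obs))
  }
})

test_that("observed equals latent exactly when mu = 0", {
  sim <- simulate_panel(sim_config(n_respondents = 300, misreport_rate = 0,
                                   uptake_probability = 0,
                                   once_probability = 0, seed = 15))
  joined <- dplyr::inner_join(tibble::as_tibble(sim$panel), sim$truth,
                              by = c("id", "wave"))
  expect_equal(joined$vol_likert, joined$latent_vol)
  expect_false(any(joined$misreport_vol))
})

test_that("misreports flip observations at the configured rate", {
  sim <- simulate_panel(sim_config(n_respondents = 3000, misreport_rate = 0.3,
                                   uptake_probability = 0,
                                   once_probability = 0, seed = 16))
  rate <- mean(sim$truth$misreport_vol)
  expect_lt(abs(rate - 0.3), mn_3se(0.3, nrow(sim$truth)))
  # shared flag couples the two regimes' misreport draws
  shared <- simulate_panel(sim_config(n_respondents = 500,
                                      misreport_rate = 0.4,
                                      misreport_shared = TRUE, seed = 17))
  expect_identical(shared$truth$misreport_vol, shared$truth$misreport_man)
})

test_that("wave-3 uptake censors the willing as designed", {
  sim <- simulate_panel(sim_config(n_respondents = 2000,
                                   uptake_probability = 0.5,
                                   once_probability = 0, seed = 18))
  final <- dplyr::filter(tibble::as_tibble(sim$panel), wave == 3)
  truth3 <- dplyr::filter(sim$truth, wave == 3)
  willing <- truth3$latent_vol >= 3
  twice <- final$vax_status == "twice"
  # only the latently willing get vaccinated twice
  expect_true(all(willing[twice]))
  # uptake rate among the willing near the configured probability
  expect_lt(abs(mean(twice[willing]) - 0.5), mn_3se(0.5, sum(willing)))
  # vaccinated twice -> attitude not asked
  expect_true(all(is.na(final$vol_likert[twice])))
  expect_true(all(is.na(final$man_likert[twice])))
})

test_that("covariate-dependent transitions shift switching as configured", {
  # positive trust pushes transitions toward higher agreement
  coefs <- list(trust_government = c(-2, -1, 0, 1, 2))
  cfg <- sim_config(n_respondents = 3000, transition_coefs = coefs,
                    uptake_probability = 0, once_probability = 0, seed = 19)
  sim <- simulate_panel(cfg)
  w12 <- dplyr::inner_join(
    dplyr::filter(sim$truth, wave == 1),
    dplyr::filter(sim$truth, wave == 2),
    by = "id", suffix = c("_1", "_2"))
  covs <- dplyr::distinct(tibble::as_tibble(sim$panel),
                          id, trust_government)
  w12 <- dplyr::inner_join(w12, covs, by = "id")
  hi <- w12$trust_government > 0.5
  lo <- w12$trust_government < -0.5
  expect_gt(mean(w12$latent_vol_2[hi]), mean(w12$latent_vol_2[lo]))
})

test_that("regime coupling makes mandated start below voluntary", {
  cfg <- sim_config(n_respondents = 1500, regime_coupling = 1,
                    regime_offset = 1, uptake_probability = 0, seed = 20)
  sim <- simulate_panel(cfg)
  w1 <- dplyr::filter(sim$truth, wave == 1)
  expect_true(all(w1$latent_man == pmax(w1$latent_vol - 1, 0)))
})

test_that("a YAML config round-trips into sim_config", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "n_respondents: 50",
    "n_waves: 3",
    "misreport_rate: 0.25",
    "seed: 4"), f)
  cfg <- sim_config_from_yaml(f)
  expect_s3_class(cfg, "sim_config")
  expect_equal(cfg$n_respondents, 50L)
  expect_equal(cfg$misreport_rate, 0.25)
  writeLines("not_a_knob: 3", f)
  expect_error(sim_config_from_yaml(f), "unknown config key")
})
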