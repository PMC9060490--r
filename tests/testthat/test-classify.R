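test_that("Likert levels collapse to the three attitude categories", {
  expect_equal(as.character(likert_category(0:4)),
               c("opposed", "opposed", "undecided", "willing", "willing"))
  expect_error(likert_category(c(1, NA)), "missing")
  expect_error(likert_category(5), "outside")
})

test_that("consistency classes are exhaustive and order-sensitive", {
  p <- panel_from_trajectories(list(
    c(0, 1, 0),   # consistently opposed
    c(2, 2, 2),   # consistently undecided
    c(4, 3, 4),   # consistently willing
    c(0, 4, 0)))  # inconsistent
  cls <- classify_consistency(p, "voluntary")
  expect_equal(as.character(cls$consistency),
               c("consistently_opposed", "consistently_undecided",
                 "consistently_willing", "inconsistent"))

  # same categories in a different wave order stay consistent only when
  # every wave matches
  p2 <- panel_from_trajectories(list(c(4, 0, 0), c(0, 0, 4)))
  cls2 <- classify_consistency(p2, "voluntary")
  expect_true(all(cls2$consistency == "inconsistent"))
})

test_that("consistency_shares reproduces hand-enumerated fixtures", {
  p <- panel_from_trajectories(list(
    c(0, 1, 1), c(3, 4, 4), c(2, 3, 2), c(4, 4, 4)))
  cs <- consistency_shares(p, "voluntary")
  expect_equal(
    cs$classes$share[cs$classes$class == "consistently_opposed"], 0.25)
  expect_equal(sum(cs$classes$share), 1, tolerance = 1e-12)
  # per-wave opposed: wave1 1/4, wave2 1/4, wave3 1/4
  expect_equal(cs$by_wave_opposed$share, c(0.25, 0.25, 0.25))
  expect_equal(cs$mean_opposed, 0.25)

  all_willing <- panel_from_trajectories(list(c(3, 3, 4), c(4, 4, 4)))
  cw <- consistency_shares(all_willing, "voluntary")
  expect_equal(
    cw$classes$share[cw$classes$class == "consistently_willing"], 1)
  expect_equal(sum(cw$classes$share[cw$classes$class != "consistently_willing"]), 0)
})

test_that("class shares sum to one on arbitrary panels", {
  for (seed in 1:5) {
    cs <- consistency_shares(random_panel(n = 40, seed = seed), "mandated")
    expect_equal(sum(cs$classes$share), 1, tolerance = 1e-12)
  }
})

test_that("degenerate chain with no noise yields zero inconsistency", {
  ident <- diag(5); dimnames(ident) <- list(from = 0:4, to = 0:4)
  sim <- simulate_panel(sim_config(
    n_respondents = 100, transitions_voluntary = ident,
    transitions_mandated = ident, misreport_rate = 0,
    uptake_probability = 0, once_probability = 0, seed = 3))
  cs <- consistency_shares(sim$panel, "voluntary")
  expect_equal(
    cs$classes$share[cs$classes$class == "inconsistent"], 0)
  # observed levels constant across waves for everyone
  spans <- sim$panel |>
    dplyr::group_by(id) |>
    dplyr::summarise(constant = length(unique(vol_likert)) == 1)
  expect_true(all(spans$constant))
})

test_that("switching tables match enumeration and sum to one", {
  # all wave-1 opposed become willing
  p <- panel_from_trajectories(purrr::map(1:5, ~ c(0, 4, 4)))
  st <- switching_table(p, "voluntary", 1, 2, "opposed")
  expect_equal(st$share[st$destination == "willing"], 1)

  # 10 opposed: 4 stay, 3 undecided, 3 willing
  traj <- c(purrr::map(1:4, ~ c(1, 0, 0)), purrr::map(1:3, ~ c(0, 2, 2)),
            purrr::map(1:3, ~ c(0, 3, 3)))
  st2 <- switching_table(panel_from_trajectories(traj), "voluntary", 1, 2,
                         "opposed")
  expect_equal(st2$share, c(0.4, 0.3, 0.3))
  expect_equal(sum(st2$count), attr(st2, "n_origin"))
  expect_equal(sum(st2$share), 1, tolerance = 1e-12)

  expect_error(switching_table(p, "voluntary", 1, 2, "undecided"),
               "no respondent")
})

test_that("switching shares agree with the generating chain's collapsed rows", {
  P <- default_transition_matrix(0.6, 0.5)
  sim <- simulate_panel(sim_config(
    n_respondents = 8000, transitions_voluntary = P,
    uptake_probability = 0, once_probability = 0, seed = 21))
  st <- switching_table(sim$panel, "voluntary", 1, 2, "opposed")

  # collapsed destination probabilities given opposed origin, weighted
  # by the wave-1 occupancy of states 0 and 1
  w1 <- table(factor(sim$panel$vol_likert[sim$panel$wave == 1], levels = 0:4))
  w_opp <- as.numeric(w1[1:2]) / sum(w1[1:2])
  dest <- w_opp[1] * P[1, ] + w_opp[2] * P[2, ]
  expected <- c(sum(dest[1:2]), dest[3], sum(dest[4:5]))
  for (k in 1:3) {
    expect_lt(abs(st$share[k] - expected[k]),
              mn_3se(expected[k], attr(st, "n_origin")))
  }
})

test_that("vaccinated-twice policy switches between exclusion and willing", {
  p <- tibble::as_tibble(panel_from_trajectories(list(c(4, 4, 4), c(0, 0, 0))))
  p$vax_status[p$id == "p001"] <- c("unvaccinated", "unvaccinated", "twice")
  p$vol_likert[p$id == "p001" & p$wave == 3] <- NA
  p <- validate_panel(p)

  excl <- consistency_shares(p, "voluntary", vaccinated = "exclude")
  expect_equal(excl$n, 1)  # only the opposed respondent is complete
  incl <- consistency_shares(p, "voluntary", vaccinated = "willing")
  expect_equal(incl$n, 2)
  expect_equal(
    incl$classes$share[incl$classes$class == "consistently_willing"], 0.5)
})
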