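# Builds small panels in code where the binary outcome has a known
# dependence on covariates, so fits can be checked against the truth.

# Panel whose consistently-opposed indicator follows a logit in the
# given covariates (standardised scale).
logit_outcome_panel <- function(n, beta, seed = 1) {
  set.seed(seed)
  covars <- tibble::tibble(
    belief = stats::rnorm(n),
    socio = stats::rnorm(n),
    group = sample(c("a", "b"), n, replace = TRUE))
  eta <- beta[["intercept"]] +
    beta[["belief"]] * covars$belief + beta[["socio"]] * covars$socio
  y <- stats::rbinom(n, 1, stats::plogis(eta))
  traj <- purrr::map(y, ~ if (.x == 1) c(0, 1, 0) else c(3, 4, 4))
  panel_from_trajectories(traj, covars = covars)
}

test_that("standardisation gives mean zero, unit sample SD, and is invertible", {
  d <- tibble::tibble(a = c(1, 2, 3), b = c(10, 10, 40), lab = c("x", "y", "z"))
  s <- standardize_columns(d, c("a", "b"))
  expect_equal(s$a, c(-1, 0, 1))        # sample SD convention
  expect_equal(mean(s$b), 0, tolerance = 1e-12)
  expect_equal(stats::sd(s$b), 1, tolerance = 1e-12)
  expect_identical(s$lab, d$lab)
  # idempotent up to numerical noise
  s2 <- standardize_columns(s, c("a", "b"))
  expect_equal(s2$a, s$a, tolerance = 1e-12)
  # scaling record inverts
  sc <- attr(s, "scaling")
  expect_equal(s$a * sc$scale[sc$column == "a"] + sc$center[sc$column == "a"],
               d$a)
  # long random column
  set.seed(1)
  r <- standardize_columns(tibble::tibble(z = stats::rnorm(1000, 5, 3)))
  expect_lt(abs(mean(r$z)), 1e-12)
  expect_equal(stats::sd(r$z), 1, tolerance = 1e-12)
  expect_error(standardize_columns(tibble::tibble(k = rep(2, 5))),
               "'k' has zero variance")
})

test_that("Tjur's R2 matches its definition on worked cases", {
  expect_identical(tjur_r2(c(0.18, 0.18, 0.03, 0.03), c(1, 1, 0, 0)),
                   0.18 - 0.03)
  expect_equal(tjur_r2(c(1, 1, 0), c(1, 1, 0)), 1)
  expect_equal(tjur_r2(rep(0.4, 6), c(1, 0, 1, 0, 1, 0)), 0)
  expect_error(tjur_r2(c(0.5, 0.5), c(1, 1)), "single class")
})

test_that("Tjur's R2 of a linear probability fit equals variance explained", {
  for (seed in 1:3) {
    set.seed(seed)
    n <- 400
    x1 <- stats::rnorm(n); x2 <- stats::rnorm(n)
    y <- as.numeric(stats::runif(n) < stats::plogis(-1 + x1 - 0.5 * x2))
    fit <- stats::lm(y ~ x1 + x2)
    r2 <- summary(fit)$r.squared
    expect_equal(tjur_r2(stats::fitted(fit), y), r2, tolerance = 1e-10)
  }
})

test_that("logit recovers known standardised coefficients at n = 10,000", {
  beta <- c(intercept = -2, belief = 0.8, socio = 0)
  p <- logit_outcome_panel(10000, beta, seed = 31)
  fit <- fit_attitude_model(p, "consistently_opposed", "voluntary",
                            predictors = c("belief", "socio", "group"))
  co <- fit$coefficients
  for (term in c("belief", "socio")) {
    row <- co[co$term == term, ]
    expect_lt(abs(row$estimate - beta[[term]]), 3 * row$std_error)
  }
  expect_gt(fit$tjur_r2, 0)
  expect_false(is.na(fit$pseudo_r2))
})

test_that("null outcomes leave coefficients inside their intervals", {
  covered <- 0; total <- 0
  for (rep in 1:25) {
    p <- logit_outcome_panel(400, c(intercept = -1, belief = 0, socio = 0),
                             seed = 100 + rep)
    fit <- fit_attitude_model(p, "consistently_opposed", "voluntary",
                              predictors = c("belief", "socio"))
    co <- fit$coefficients[fit$coefficients$term %in% c("belief", "socio"), ]
    covered <- covered + sum(co$conf_low <= 0 & co$conf_high >= 0)
    total <- total + nrow(co)
  }
  expect_gte(covered / total, 0.9)
})

test_that("degenerate outcomes raise a diagnostic error", {
  p <- panel_from_trajectories(purrr::map(1:20, ~ c(0, 0, 0)),
                               covars = tibble::tibble(z = stats::rnorm(20)))
  expect_error(
    fit_attitude_model(p, "consistently_opposed", "voluntary",
                       predictors = "z"),
    "degenerate")
})

test_that("switching outcome conditions on wave-2 opposition", {
  # 4 opposed in wave 2: 2 move to willing; 1 willing respondent excluded
  traj <- list(c(0, 0, 4), c(0, 1, 3), c(0, 0, 0), c(0, 1, 2), c(4, 4, 4))
  out <- panel_outcome(panel_from_trajectories(traj),
                       "moved_opposed_to_willing", "voluntary")
  expect_equal(nrow(out), 4)
  expect_equal(sum(out$y), 2)
})

test_that("model comparison isolates the explanatory power of beliefs", {
  beta <- c(intercept = -1.5, belief = 1.2, socio = 0)
  p <- logit_outcome_panel(4000, beta, seed = 41)
  cmp <- compare_attitude_models(p, "consistently_opposed", "voluntary",
                                 sociodemographics = c("socio", "group"),
                                 beliefs = "belief")
  expect_equal(cmp$full$n, cmp$sociodemographic$n)
  expect_lt(cmp$sociodemographic$tjur_r2, 0.02)
  expect_gt(cmp$full$tjur_r2, cmp$sociodemographic$tjur_r2 + 0.05)

  # outcome driven by the sociodemographic instead: both models tie
  beta2 <- c(intercept = -1.5, belief = 0, socio = 1.2)
  p2 <- logit_outcome_panel(4000, beta2, seed = 42)
  cmp2 <- compare_attitude_models(p2, "consistently_opposed", "voluntary",
                                  sociodemographics = c("socio", "group"),
                                  beliefs = "belief")
  expect_lt(abs(cmp2$delta_tjur), 0.02)

  # pure-noise outcome: both near zero
  beta3 <- c(intercept = -1, belief = 0, socio = 0)
  p3 <- logit_outcome_panel(4000, beta3, seed = 43)
  cmp3 <- compare_attitude_models(p3, "consistently_opposed", "voluntary",
                                  sociodemographics = c("socio", "group"),
                                  beliefs = "belief")
  expect_lt(cmp3$full$tjur_r2, 0.02)
  expect_lt(cmp3$sociodemographic$tjur_r2, 0.02)
  expect_error(
    compare_attitude_models(p3, "consistently_opposed", "voluntary",
                            sociodemographics = "socio", beliefs = "socio"),
    "disjoint")
})
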