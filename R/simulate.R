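# Synthetic three-wave attitude panels. The generator reproduces the
# statistical structure the analyses assume -- first-order Markov
# transitions between the five Likert states (optionally
# covariate-dependent via a multinomial-logit link), independent
# uniform-misreport contamination at rate mu, optional coupling of the
# mandated chain to the voluntary one, and vaccination uptake among the
# willing by the final wave -- so every downstream stage can be tested
# against known ground truth.

#' Default attitude transition matrix for simulations
#'
#' A sticky five-state chain with net drift toward willingness: most
#' respondents keep their level between waves, movement away from
#' opposition is more likely than movement into it. Used when a
#' simulation config supplies no matrix of its own.
#'
#' @param stay Probability of keeping the current level (default 0.7).
#' @param up_bias Fraction of the remaining mass moving toward higher
#'   agreement rather than lower (default 0.7).
#' @return A 5x5 row-stochastic matrix with Likert-level dimnames.
#' @export
default_transition_matrix <- function(stay = 0.7, up_bias = 0.7) {
  stopifnot(stay > 0, stay < 1, up_bias >= 0, up_bias <= 1)
  P <- matrix(0, 5, 5, dimnames = list(from = 0:4, to = 0:4))
  for (i in 1:5) {
    move <- 1 - stay
    below <- i - 1; above <- 5 - i
    w <- numeric(5)
    if (above > 0) w[(i + 1):5] <- up_bias * move * (1 / 2)^(seq_len(above))
    if (below > 0) w[(i - 1):1] <- (1 - up_bias) * move * (1 / 2)^(seq_len(below))
    if (above == 0) w[1:below] <- w[1:below] / sum(w[1:below]) * move
    if (below == 0) w[(i + 1):5] <- w[(i + 1):5] / sum(w[(i + 1):5]) * move
    if (above > 0 && below > 0) w <- w / sum(w) * move
    w[i] <- stay
    P[i, ] <- w / sum(w)
  }
  P
}

#' Build a simulation configuration
#'
#' Collects everything the generator needs. Defaults emulate the study
#' panel: 2,018 respondents over three waves; voluntary-regime
#' opposition around 17% per wave but fluid, so only a few percent stay
#' opposed in all three waves; mandated-regime opposition around a third
#' per wave and far stickier; no misreports; and 90% vaccination uptake
#' among the finally willing.
#'
#' @param n_respondents Number of respondents (default 2018).
#' @param n_waves Number of waves, at least 2 (default 3).
#' @param initial_voluntary,initial_mandated Probability vectors of
#'   length 5 over Likert levels 0--4 at wave 1.
#' @param transitions_voluntary,transitions_mandated 5x5 row-stochastic
#'   transition matrices for the latent chains.
#' @param transition_coefs Optional named list for covariate-dependent
#'   transitions: each element is a length-5 numeric vector of
#'   multinomial-logit shifts added to the log baseline row, scaled by
#'   the respondent's (numeric) covariate of that name. `NULL` keeps the
#'   homogeneous chain.
#' @param misreport_rate Misreport probability mu in `[0, 1]`: with this
#'   probability the observed response is uniform over the five levels
#'   instead of the latent level, independently per wave (default 0).
#' @param misreport_shared If `TRUE`, one misreport draw per
#'   respondent-wave is shared by both regime questions; if `FALSE`
#'   (default) the regimes misreport independently.
#' @param regime_coupling Probability in `[0, 1]` that a respondent's
#'   mandated wave-1 state is their voluntary state shifted down by
#'   `regime_offset` rather than an independent draw (default 0).
#' @param regime_offset Downward Likert shift applied under coupling
#'   (default 1; mandated attitudes run more oppositional).
#' @param uptake_probability Probability that a respondent whose latent
#'   voluntary level is 3 or 4 at the final wave is vaccinated twice by
#'   then (default 0.9).
#' @param once_probability Probability that a willing-but-not-twice
#'   respondent is vaccinated once by the final wave (default 0.1).
#' @param covariates List of covariate specs, each a list with `name`,
#'   `kind` (`"categorical"` or `"numeric"`), and either `levels` +
#'   `probs` or `mean` + `sd`.
#' @param seed Integer seed; one seed fully determines the panel.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_respondents = 2018,
                       n_waves = 3,
                       initial_voluntary = c(0.10, 0.06, 0.12, 0.22, 0.50),
                       initial_mandated = c(0.30, 0.16, 0.16, 0.16, 0.22),
                       transitions_voluntary = default_transition_matrix(0.25, 0.92),
                       transitions_mandated = default_transition_matrix(0.85, 0.35),
                       transition_coefs = NULL,
                       misreport_rate = 0,
                       misreport_shared = FALSE,
                       regime_coupling = 0,
                       regime_offset = 1,
                       uptake_probability = 0.9,
                       once_probability = 0.1,
                       covariates = default_covariates(),
                       seed = 1L) {
  stopifnot(n_respondents >= 1, n_waves >= 2)
  for (v in list(initial_voluntary, initial_mandated)) {
    if (length(v) != 5 || any(v < 0) || abs(sum(v) - 1) > 1e-12) {
      stop("initial distributions must be length-5 probability vectors ",
           "summing to 1 (tolerance 1e-12)", call. = FALSE)
    }
  }
  for (M in list(transitions_voluntary, transitions_mandated)) {
    if (!all(dim(M) == c(5, 5)) || any(M < 0) ||
        any(abs(rowSums(M) - 1) > 1e-12)) {
      stop("transition matrices must be 5x5 row-stochastic", call. = FALSE)
    }
  }
  for (p in c(misreport_rate, regime_coupling, uptake_probability,
              once_probability)) {
    if (p < 0 || p > 1) stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  structure(list(
    n_respondents = as.integer(n_respondents), n_waves = as.integer(n_waves),
    initial_voluntary = initial_voluntary, initial_mandated = initial_mandated,
    transitions_voluntary = transitions_voluntary,
    transitions_mandated = transitions_mandated,
    transition_coefs = transition_coefs,
    misreport_rate = misreport_rate, misreport_shared = misreport_shared,
    regime_coupling = regime_coupling, regime_offset = regime_offset,
    uptake_probability = uptake_probability,
    once_probability = once_probability,
    covariates = covariates, seed = as.integer(seed)),
    class = "sim_config")
}

#' Default covariate specification for synthetic panels
#'
#' Region (East/West at the German population split), sex, age, a
#' trust-in-institutions index and a perceived-vaccine-risk score, the
#' latter two standardised-scale beliefs that downstream regressions can
#' use as predictors.
#'
#' @return A list of covariate specs for [sim_config()].
#' @export
default_covariates <- function() {
  list(
    list(name = "region", kind = "categorical",
         levels = c("West", "East"), probs = c(0.8, 0.2)),
    list(name = "sex", kind = "categorical",
         levels = c("female", "male"), probs = c(0.51, 0.49)),
    list(name = "age", kind = "numeric", mean = 50, sd = 16),
    list(name = "trust_government", kind = "numeric", mean = 0, sd = 1),
    list(name = "vaccine_risk", kind = "numeric", mean = 0, sd = 1)
  )
}

draw_covariates <- function(cfg) {
  n <- cfg$n_respondents
  out <- tibble::tibble(id = sprintf("s%05d", seq_len(n)))
  for (cv in cfg$covariates) {
    out[[cv$name]] <- if (cv$kind == "categorical") {
      sample(cv$levels, n, replace = TRUE, prob = cv$probs)
    } else {
      stats::rnorm(n, cv$mean, cv$sd)
    }
  }
  out
}

# Transition row for state i, shifted on the logit scale by covariates.
transition_row <- function(P, i, cfg, covs_row) {
  row <- P[i, ]
  if (is.null(cfg$transition_coefs)) return(row)
  eta <- log(pmax(row, 1e-12))
  for (nm in names(cfg$transition_coefs)) {
    z <- covs_row[[nm]]
    if (is.null(z)) stop("transition_coefs names unknown covariate: ", nm,
                         call. = FALSE)
    eta <- eta + cfg$transition_coefs[[nm]] * as.numeric(z)
  }
  p <- exp(eta - max(eta))
  p / sum(p)
}

sample_chain <- function(init, P, cfg, covs_row, W) {
  s <- integer(W)
  s[1] <- sample.int(5, 1, prob = init)
  for (w in 2:W) {
    s[w] <- sample.int(5, 1, prob = transition_row(P, s[w - 1], cfg, covs_row))
  }
  s - 1L  # Likert levels 0..4
}

#' Simulate a synthetic attitude panel with ground truth
#'
#' Draws each respondent's latent voluntary and mandated Likert
#' trajectories from the configured Markov chains, contaminates the
#' observed responses with uniform misreports at rate `mu`, assigns
#' final-wave vaccination status among the willing, and censors the
#' attitude responses of those vaccinated twice (they were not asked).
#' The observable panel and the latent truth are returned separately so
#' recovery tests never peek.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_panel` with elements `panel` (a
#'   `vax_panel` tibble as [read_panel()] would return) and `truth` (a
#'   tibble of latent levels and misreport flags per respondent-wave).
#' @export
simulate_panel <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_respondents
  W <- config$n_waves

  covs <- draw_covariates(config)

  lat_vol <- matrix(NA_integer_, n, W)
  lat_man <- matrix(NA_integer_, n, W)
  for (i in seq_len(n)) {
    covs_row <- covs[i, ]
    lat_vol[i, ] <- sample_chain(config$initial_voluntary,
                                 config$transitions_voluntary,
                                 config, covs_row, W)
    if (stats::runif(1) < config$regime_coupling) {
      start <- max(0L, lat_vol[i, 1] - config$regime_offset)
      s <- integer(W); s[1] <- start + 1L
      for (w in 2:W) {
        s[w] <- sample.int(5, 1, prob = transition_row(
          config$transitions_mandated, s[w - 1], config, covs_row))
      }
      lat_man[i, ] <- s - 1L
    } else {
      lat_man[i, ] <- sample_chain(config$initial_mandated,
                                   config$transitions_mandated,
                                   config, covs_row, W)
    }
  }

  # misreports: uniform over the 5 levels with probability mu
  mis_vol <- matrix(stats::runif(n * W) < config$misreport_rate, n, W)
  mis_man <- if (config$misreport_shared) mis_vol else
    matrix(stats::runif(n * W) < config$misreport_rate, n, W)
  ran_vol <- matrix(sample(0:4, n * W, replace = TRUE), n, W)
  ran_man <- matrix(sample(0:4, n * W, replace = TRUE), n, W)
  obs_vol <- ifelse(mis_vol, ran_vol, lat_vol)
  obs_man <- ifelse(mis_man, ran_man, lat_man)

  # vaccination uptake among the finally willing (latent voluntary 3/4)
  willing_final <- lat_vol[, W] >= 3
  u <- stats::runif(n)
  status_final <- ifelse(willing_final & u < config$uptake_probability,
                         "twice",
                         ifelse(willing_final &
                                  u < config$uptake_probability +
                                      config$once_probability,
                                "once", "unvaccinated"))

  panel <- tidyr::expand_grid(idx = seq_len(n), wave = seq_len(W)) |>
    dplyr::mutate(
      id = covs$id[.data$idx],
      vol_likert = obs_vol[cbind(.data$idx, .data$wave)],
      man_likert = obs_man[cbind(.data$idx, .data$wave)],
      vax_status = ifelse(.data$wave == W, status_final[.data$idx],
                          "unvaccinated")) |>
    dplyr::left_join(covs, by = "id") |>
    dplyr::select(-"idx") |>
    dplyr::relocate("id")

  # those vaccinated twice at a wave were not asked the attitude items
  asked_out <- panel$vax_status == "twice"
  panel$vol_likert[asked_out] <- NA_integer_
  panel$man_likert[asked_out] <- NA_integer_

  truth <- tidyr::expand_grid(idx = seq_len(n), wave = seq_len(W)) |>
    dplyr::mutate(
      id = covs$id[.data$idx],
      latent_vol = lat_vol[cbind(.data$idx, .data$wave)],
      latent_man = lat_man[cbind(.data$idx, .data$wave)],
      misreport_vol = mis_vol[cbind(.data$idx, .data$wave)],
      misreport_man = mis_man[cbind(.data$idx, .data$wave)]) |>
    dplyr::select(-"idx") |>
    dplyr::relocate("id")

  structure(list(panel = validate_panel(panel), truth = truth,
                 config = config),
            class = "sim_panel")
}

#' @export
print.sim_panel <- function(x, ...) {
  cat("Synthetic attitude panel:", x$config$n_respondents, "respondents x",
      x$config$n_waves, "waves (seed", x$config$seed, ")\n")
  print(x$panel, n = 6)
  invisible(x)
}

#' Simulate the misreport model's opposed indicators directly
#'
#' Forward-simulates the measurement model alone, without the Markov
#' layer: a fraction `x` of respondents is truly and invariantly
#' opposed; each wave, a truly opposed respondent records opposition
#' with probability `1 - p_not * mu` and anyone else with probability
#' `p_opp * mu`. Used for Monte-Carlo checks of the closed-form shares
#' and of [solve_error_model()].
#'
#' @param x True invariant opposed fraction.
#' @param mu Random-response rate.
#' @param n Number of simulated respondents.
#' @param spec An [error_model_spec()]; its `waves` sets the panel length.
#' @param seed Optional integer seed.
#' @return A tibble with `id`, `truly_opposed`, one logical
#'   `opposed_w<k>` column per wave, `consistent` (opposed in every
#'   wave), and attribute `shares`: list with the empirical
#'   `consistent` share and `mean_cross_section` share.
#' @export
simulate_error_model_population <- function(x, mu, n,
                                            spec = error_model_spec(),
                                            seed = NULL) {
  check_unit(x, "x"); check_unit(mu, "mu")
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  W <- spec$waves
  truly <- stats::runif(n) < x
  p_obs <- ifelse(truly, 1 - spec$p_not * mu, spec$p_opp * mu)
  obs <- matrix(stats::runif(n * W), n, W) < p_obs
  colnames(obs) <- paste0("opposed_w", seq_len(W))
  out <- dplyr::bind_cols(
    tibble::tibble(id = seq_len(n), truly_opposed = truly),
    tibble::as_tibble(obs))
  out$consistent <- rowSums(obs) == W
  attr(out, "shares") <- list(
    consistent = mean(out$consistent),
    mean_cross_section = mean(colMeans(obs)))
  out
}

#' Read a simulation configuration from a YAML file
#'
#' Accepts a YAML mapping whose keys mirror the arguments of
#' [sim_config()]; transition matrices are given as lists of five
#' 5-element rows. Keys not present fall back to the defaults.
#'
#' @param path Path to a YAML file.
#' @return A validated [sim_config()].
#' @export
sim_config_from_yaml <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  for (key in c("transitions_voluntary", "transitions_mandated")) {
    if (!is.null(raw[[key]])) {
      raw[[key]] <- do.call(rbind, raw[[key]])
      dimnames(raw[[key]]) <- list(from = 0:4, to = 0:4)
    }
  }
  unknown <- setdiff(names(raw), names(formals(sim_config)))
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(sim_config, raw)
}
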