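# Fixture builders used across test files. All panels are built in code.

# A panel from per-respondent voluntary trajectories (mandated mirrors
# voluntary unless given), everyone unvaccinated.
panel_from_trajectories <- function(vol, man = vol, covars = NULL) {
  n <- length(vol)
  W <- length(vol[[1]])
  out <- purrr::map_dfr(seq_len(n), function(i) {
    tibble::tibble(
      id = sprintf("p%03d", i), wave = seq_len(W),
      vol_likert = as.integer(vol[[i]]),
      man_likert = as.integer(man[[i]]),
      vax_status = "unvaccinated")
  })
  if (!is.null(covars)) {
    covars$id <- sprintf("p%03d", seq_len(n))
    out <- dplyr::left_join(out, covars, by = "id")
  }
  validate_panel(out)
}

# Random valid panel for property-style loops.
random_panel <- function(n = 50, W = 3, seed = 1) {
  set.seed(seed)
  panel_from_trajectories(
    purrr::map(seq_len(n), ~ sample(0:4, W, replace = TRUE)),
    purrr::map(seq_len(n), ~ sample(0:4, W, replace = TRUE)))
}

# Multinomial 3-sigma band for an estimated transition probability.
mn_3se <- function(p, n) 3 * sqrt(p * (1 - p) / n) + 1e-12

# Same confidence as a single 3-sigma band, Bonferroni-adjusted for a
# family of simultaneous comparisons (e.g. all 25 cells of a 5x5
# matrix), so the joint check keeps the per-comparison error rate.
mn_joint_band <- function(p, n, n_tests) {
  z <- stats::qnorm(1 - stats::pnorm(-3) / n_tests)
  z * sqrt(p * (1 - p) / n) + 1e-12
}
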