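# Attitude dynamics as a discrete-time Markov chain: estimate transition
# matrices from paired waves, solve for the stationary (long-run
# equilibrium) distribution, and project hypothetical trajectories.

state_labels <- function(state_space = c("likert5", "collapsed3")) {
  switch(match.arg(state_space),
         likert5 = as.character(0:4),
         collapsed3 = attitude_levels())
}

#' Estimate an attitude transition matrix from paired waves
#'
#' Maximum-likelihood row-stochastic estimate: `P[i, j]` is the fraction
#' of respondents in state `i` at `from_wave` observed in state `j` at
#' `to_wave`. States are the five Likert levels or the three collapsed
#' categories. Respondents missing either wave (including those
#' vaccinated twice, who were not asked) are excluded. An origin state
#' with no respondents gets a self-loop row by default (flagged in
#' `empty_states`), or a uniform row with `empty = "uniform"`; optional
#' Laplace smoothing adds `alpha` pseudo-counts to every cell.
#'
#' @param panel A panel table.
#' @param regime `"voluntary"` or `"mandated"`.
#' @param from_wave,to_wave Wave pair to pair up.
#' @param state_space `"likert5"` (default) or `"collapsed3"`.
#' @param empty Rule for origin states with zero observations:
#'   `"self"` (stay put) or `"uniform"`.
#' @param alpha Laplace pseudo-count added to every transition cell
#'   (default 0, no smoothing).
#' @return An object of class `transition_matrix`: list with `P`
#'   (row-stochastic matrix), `counts`, `states`, `source_waves`,
#'   `empty_states`, `n`.
#' @export
estimate_transitions <- function(panel, regime = c("voluntary", "mandated"),
                                 from_wave, to_wave,
                                 state_space = c("likert5", "collapsed3"),
                                 empty = c("self", "uniform"),
                                 alpha = 0) {
  regime <- match.arg(regime)
  state_space <- match.arg(state_space)
  empty <- match.arg(empty)
  stopifnot(alpha >= 0)
  panel <- validate_panel(panel)
  col <- likert_col(regime)

  pair <- panel |>
    dplyr::filter(.data$wave %in% c(from_wave, to_wave)) |>
    dplyr::select("id", "wave", level = dplyr::all_of(col)) |>
    tidyr::pivot_wider(names_from = "wave", values_from = "level") |>
    dplyr::rename(from = dplyr::all_of(as.character(from_wave)),
                  to = dplyr::all_of(as.character(to_wave))) |>
    dplyr::filter(!is.na(.data$from), !is.na(.data$to))
  if (nrow(pair) == 0) stop("no paired observations between waves ",
                            from_wave, " and ", to_wave, call. = FALSE)

  labels <- state_labels(state_space)
  if (state_space == "collapsed3") {
    from_s <- likert_category(pair$from)
    to_s <- likert_category(pair$to)
  } else {
    from_s <- factor(pair$from, levels = 0:4)
    to_s <- factor(pair$to, levels = 0:4)
  }
  counts <- table(from = from_s, to = to_s)
  counts <- matrix(as.numeric(counts), nrow = length(labels),
                   dimnames = list(from = labels, to = labels))

  smoothed <- counts + alpha
  row_tot <- rowSums(smoothed)
  empty_states <- labels[rowSums(counts) == 0 & alpha == 0]
  P <- smoothed / ifelse(row_tot > 0, row_tot, 1)
  for (s in empty_states) {
    P[s, ] <- if (empty == "self") {
      as.numeric(labels == s)
    } else {
      rep(1 / length(labels), length(labels))
    }
  }

  new_transition_matrix(P, counts = counts, states = labels,
                        source_waves = c(from = from_wave, to = to_wave),
                        empty_states = empty_states, n = nrow(pair))
}

#' Construct a transition-matrix object from a row-stochastic matrix
#'
#' @param P Square numeric matrix, rows summing to 1.
#' @param counts Optional matrix of underlying paired counts.
#' @param states Character state labels (default from `P`'s dimnames).
#' @param source_waves,empty_states,n Metadata carried along.
#' @return An object of class `transition_matrix`.
#' @export
new_transition_matrix <- function(P, counts = NULL, states = NULL,
                                  source_waves = NULL,
                                  empty_states = character(), n = NA_integer_) {
  P <- as.matrix(P)
  stopifnot(nrow(P) == ncol(P))
  if (any(P < -1e-12) || any(P > 1 + 1e-12)) {
    stop("transition probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (any(abs(rowSums(P) - 1) > 1e-10)) {
    stop("every transition row must sum to 1 (tolerance 1e-10)",
         call. = FALSE)
  }
  if (is.null(states)) states <- rownames(P) %||% as.character(seq_len(nrow(P)))
  dimnames(P) <- list(from = states, to = states)
  structure(list(P = P, counts = counts, states = states,
                 source_waves = source_waves, empty_states = empty_states,
                 n = n),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, digits = 3, ...) {
  cat("Transition matrix over states:", paste(x$states, collapse = ", "), "\n")
  if (!is.null(x$source_waves)) {
    cat("Estimated from waves", x$source_waves[["from"]], "->",
        x$source_waves[["to"]], "on n =", x$n, "respondents\n")
  }
  print(round(x$P, digits))
  if (length(x$empty_states) > 0) {
    cat("Unobserved origin state(s):", paste(x$empty_states, collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' @method tidy transition_matrix
#' @export
tidy.transition_matrix <- function(x, ...) {
  out <- as.data.frame.table(x$P, responseName = "probability",
                             stringsAsFactors = FALSE)
  out <- tibble::as_tibble(out)
  if (!is.null(x$counts)) {
    cnt <- as.data.frame.table(x$counts, responseName = "count",
                               stringsAsFactors = FALSE)
    out$count <- cnt$count
  }
  out
}

as_P <- function(P) if (inherits(P, "transition_matrix")) P$P else as.matrix(P)

# Closed communicating classes of the chain's support graph; used to
# diagnose reducible chains whose stationary vector is not unique.
closed_classes <- function(P, tol = 1e-12) {
  A <- as_P(P) > tol
  n <- nrow(A)
  reach <- A | diag(TRUE, n)
  for (k in seq_len(n)) {            # Floyd-Warshall boolean closure
    reach <- reach | outer(reach[, k], reach[k, ])
  }
  comm <- reach & t(reach)
  classes <- unique(apply(comm, 1, function(r) which(r), simplify = FALSE))
  keep <- vapply(classes, function(cl) {
    all(rowSums(as_P(P)[cl, setdiff(seq_len(n), cl), drop = FALSE]) < tol)
  }, logical(1))
  classes[keep]
}

#' Stationary distribution of an attitude chain
#'
#' Solves `pi P = pi`, `sum(pi) = 1` by replacing one balance equation
#' with the normalisation constraint, and cross-checks the solution with
#' power iteration. The stationary vector is the long-run equilibrium:
#' the flow leaving each attitude state is exactly offset by the flow
#' arriving. Chains with more than one closed communicating class have
#' no unique stationary vector and raise an error naming the classes.
#'
#' @param P A `transition_matrix` object or row-stochastic matrix.
#' @param tol Residual tolerance on the max-norm of `pi P - pi`.
#' @param max_iter Power-iteration cap for the internal cross-check.
#' @return An object of class `stationary_distribution`: list with `pi`
#'   (named probability vector), `residual`, `power_residual` (gap to
#'   the power-iteration solution), `iterations`.
#' @export
stationary_distribution <- function(P, tol = 1e-10, max_iter = 1e6) {
  M <- as_P(P)
  n <- nrow(M)
  if (any(abs(rowSums(M) - 1) > 1e-10)) {
    stop("P must be row-stochastic", call. = FALSE)
  }
  cls <- closed_classes(M)
  if (length(cls) > 1) {
    labs <- vapply(cls, function(cl) {
      paste0("{", paste(colnames(M)[cl] %||% cl, collapse = ","), "}")
    }, character(1))
    stop("chain is reducible with multiple closed classes ",
         paste(labs, collapse = " and "),
         "; the stationary distribution is not unique", call. = FALSE)
  }

  # pi (P - I) = 0 with the last column replaced by the normalisation
  A <- t(M) - diag(n)
  A[n, ] <- 1
  b <- c(rep(0, n - 1), 1)
  pi_hat <- solve(A, b)
  pi_hat[abs(pi_hat) < 1e-15] <- 0
  if (any(pi_hat < -1e-8)) {
    stop("linear solve produced a negative stationary entry", call. = FALSE)
  }
  pi_hat <- pmax(pi_hat, 0)
  pi_hat <- pi_hat / sum(pi_hat)
  residual <- max(abs(drop(pi_hat %*% M) - pi_hat))
  if (residual > tol) {
    stop("stationary solve failed to meet tolerance: residual ", residual,
         call. = FALSE)
  }

  # independent check: power iteration from the uniform distribution
  v <- rep(1 / n, n)
  iter <- 0L
  repeat {
    v_new <- drop(v %*% M)
    iter <- iter + 1L
    if (max(abs(v_new - v)) < tol / 10 || iter >= max_iter) break
    v <- v_new
  }
  names(pi_hat) <- colnames(M)
  structure(list(pi = pi_hat, residual = residual,
                 power_residual = max(abs(v_new - pi_hat)),
                 iterations = iter),
            class = "stationary_distribution")
}

#' @export
print.stationary_distribution <- function(x, digits = 4, ...) {
  cat("Stationary distribution (residual ", format(x$residual, digits = 3),
      "):\n", sep = "")
  print(round(x$pi, digits))
  invisible(x)
}

#' @method tidy stationary_distribution
#' @export
tidy.stationary_distribution <- function(x, ...) {
  tibble::tibble(state = names(x$pi) %||% as.character(seq_along(x$pi)),
                 probability = unname(x$pi))
}

#' Project a distribution forward through the chain
#'
#' Computes `initial %*% P^k` for `k = 0, ..., n_steps`. For an
#' irreducible aperiodic chain the sequence converges to the stationary
#' distribution; the thought experiment asks what the population would
#' look like if current switching rates were sustained.
#'
#' @param initial Probability vector over the chain's states.
#' @param P A `transition_matrix` or row-stochastic matrix.
#' @param n_steps Number of steps (non-negative integer).
#' @return A tibble with columns `step`, one column per state.
#' @export
project_chain <- function(initial, P, n_steps) {
  M <- as_P(P)
  initial <- as.numeric(initial)
  if (length(initial) != nrow(M)) {
    stop("initial distribution has length ", length(initial),
         " but the chain has ", nrow(M), " states", call. = FALSE)
  }
  if (abs(sum(initial) - 1) > 1e-8 || any(initial < 0)) {
    stop("initial must be a probability vector", call. = FALSE)
  }
  stopifnot(n_steps >= 0)
  states <- colnames(M) %||% as.character(seq_len(nrow(M)))
  out <- matrix(NA_real_, nrow = n_steps + 1, ncol = nrow(M),
                dimnames = list(NULL, states))
  v <- initial
  out[1, ] <- v
  for (k in seq_len(n_steps)) {
    v <- drop(v %*% M)
    out[k + 1, ] <- v
  }
  dplyr::bind_cols(tibble::tibble(step = 0:n_steps),
                   tibble::as_tibble(out))
}

#' Bootstrap the stationary distribution over respondents
#'
#' Resamples respondents with replacement, re-estimates the transition
#' matrix and its stationary distribution, and returns percentile
#' intervals. Provided instead of delta-method intervals because
#' resampling whole respondents is well defined on a panel.
#'
#' @inheritParams estimate_transitions
#' @param n_boot Number of bootstrap replicates.
#' @param conf Confidence level for the percentile interval.
#' @param seed Optional integer seed for reproducibility.
#' @return A tibble with one row per state: `estimate`, `lower`, `upper`.
#' @export
bootstrap_stationary <- function(panel, regime = c("voluntary", "mandated"),
                                 from_wave, to_wave,
                                 state_space = c("likert5", "collapsed3"),
                                 n_boot = 200, conf = 0.95, seed = NULL) {
  regime <- match.arg(regime)
  state_space <- match.arg(state_space)
  if (!is.null(seed)) set.seed(seed)
  panel <- validate_panel(panel)
  tm <- estimate_transitions(panel, regime, from_wave, to_wave, state_space)
  point <- stationary_distribution(tm)$pi

  ids <- unique(panel$id)
  draws <- matrix(NA_real_, nrow = n_boot, ncol = length(point))
  for (b in seq_len(n_boot)) {
    take <- sample(ids, length(ids), replace = TRUE)
    boot <- purrr::map_dfr(seq_along(take), function(i) {
      rows <- panel[panel$id == take[i], ]
      rows$id <- paste0("b", i)
      rows
    })
    est <- try(stationary_distribution(
      estimate_transitions(boot, regime, from_wave, to_wave, state_space)),
      silent = TRUE)
    if (!inherits(est, "try-error")) draws[b, ] <- est$pi
  }
  alpha <- (1 - conf) / 2
  qs <- apply(draws, 2, stats::quantile, probs = c(alpha, 1 - alpha),
              na.rm = TRUE)
  tibble::tibble(state = names(point), estimate = unname(point),
                 lower = qs[1, ], upper = qs[2, ])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
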