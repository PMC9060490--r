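# Random-misreport mixture model. With probability mu a respondent picks
# one of the K Likert items uniformly at random; m of the K items count
# as "opposed". Two observed moments -- the share consistently opposed in
# all W waves and the mean single-wave opposed share -- identify the true
# invariant opposed fraction x and the error rate mu. Because the model
# attributes all attitude change to noise, the solved x is an upper
# bound on hard-core opposition, not a point estimate of it.

#' Specify the misreport-model geometry
#'
#' @param K Number of Likert categories (default 5).
#' @param m Size of the opposed response set (default 2: levels 0 and 1).
#' @param waves Number of panel waves W (default 3).
#' @return A list of class `error_model_spec` with `K`, `m`, `waves`,
#'   and the derived probabilities `p_opp = m/K` (a random pick lands in
#'   the opposed set) and `p_not = 1 - m/K`.
#' @export
error_model_spec <- function(K = 5, m = 2, waves = 3) {
  stopifnot(K >= 2, m >= 1, m < K, waves >= 1,
            K %% 1 == 0, m %% 1 == 0, waves %% 1 == 0)
  structure(list(K = as.integer(K), m = as.integer(m),
                 waves = as.integer(waves),
                 p_opp = m / K, p_not = 1 - m / K),
            class = "error_model_spec")
}

check_unit <- function(x, name) {
  if (any(x < 0 | x > 1)) stop(name, " must lie in [0, 1]", call. = FALSE)
  x
}

#' Model-implied share consistently opposed in all waves
#'
#' A truly opposed respondent records opposition in one wave with
#' probability `1 - p_not * mu` (no misreport, or a misreport landing in
#' the opposed set), hence in all W waves with that probability to the
#' W-th power; a truly not-opposed respondent records opposition only
#' through misreports, with per-wave probability `p_opp * mu`.
#'
#' @param x True invariant opposed fraction, in `[0, 1]`.
#' @param mu Random-response rate, in `[0, 1]`.
#' @param spec An [error_model_spec()].
#' @return `x (1 - p_not mu)^W + (1 - x)(p_opp mu)^W`. Vectorised over
#'   `x` and `mu`.
#' @export
#' @examples
#' forward_consistent_share(0.059, 0.322)  # about 0.033
forward_consistent_share <- function(x, mu, spec = error_model_spec()) {
  check_unit(x, "x"); check_unit(mu, "mu")
  W <- spec$waves
  x * (1 - spec$p_not * mu)^W + (1 - x) * (spec$p_opp * mu)^W
}

#' Model-implied single-wave opposed share
#'
#' The W = 1 case of [forward_consistent_share()]: the expected opposed
#' share in any one cross-section.
#'
#' @inheritParams forward_consistent_share
#' @return `x (1 - p_not mu) + (1 - x) p_opp mu`. Vectorised.
#' @export
forward_cross_section_share <- function(x, mu, spec = error_model_spec()) {
  check_unit(x, "x"); check_unit(mu, "mu")
  x * (1 - spec$p_not * mu) + (1 - x) * spec$p_opp * mu
}

# Residual of the consistency equation after eliminating x through the
# linear cross-section equation: x = (a - p_opp*mu) / (1 - mu), mu < 1.
consistency_residual <- function(mu, c_obs, a_obs, spec) {
  x <- (a_obs - spec$p_opp * mu) / (1 - mu)
  forward_consistent_share_unchecked(x, mu, spec) - c_obs
}

forward_consistent_share_unchecked <- function(x, mu, spec) {
  W <- spec$waves
  x * (1 - spec$p_not * mu)^W + (1 - x) * (spec$p_opp * mu)^W
}

#' Solve the misreport model for the true opposed fraction and error rate
#'
#' Given the observed consistent-opposed share `c_obs` and the observed
#' mean cross-section opposed share `a_obs`, finds all pairs
#' `(x, mu)` in the unit square satisfying
#' \deqn{x (1 - p_{not}\mu)^W + (1 - x)(p_{opp}\mu)^W = c}
#' \deqn{x (1 - p_{not}\mu) + (1 - x) p_{opp}\mu = a}
#' by eliminating `x` through the linear second equation
#' (`x = (a - p_opp mu) / (1 - mu)`), scanning the residual of the first
#' equation on a dense grid in `mu`, and refining each sign change by
#' bisection. `mu = 1` is excluded (x is undefined there). When several
#' admissible roots exist, the primary solution is the one with the
#' smallest `mu` -- the most conservative attribution of response error --
#' and all roots are returned with an ambiguity flag.
#'
#' @param c_obs Observed share opposed in every one of the W waves.
#' @param a_obs Observed mean single-wave opposed share. Must satisfy
#'   `c_obs <= a_obs`.
#' @param spec An [error_model_spec()].
#' @param grid_n Number of grid points in `mu` for the sign scan.
#' @param tol Bisection residual tolerance.
#' @return An object of class `error_model_fit`: list with `x`, `mu`
#'   (the primary root), `roots` (tibble of all admissible roots with
#'   residuals of both equations), `unique` flag, the inputs and `spec`.
#' @export
#' @examples
#' solve_error_model(0.033, 0.169)  # x ~ 0.059, mu ~ 0.322
solve_error_model <- function(c_obs, a_obs, spec = error_model_spec(),
                              grid_n = 1e5, tol = 1e-12) {
  if (c_obs <= 0 || c_obs >= 1 || a_obs <= 0 || a_obs >= 1) {
    stop("c_obs and a_obs must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (c_obs > a_obs + 1e-12) {
    stop("c_obs (consistent share over ", spec$waves,
         " waves) cannot exceed a_obs (single-wave share)", call. = FALSE)
  }

  mu_grid <- seq(0, 1 - 1e-9, length.out = grid_n)
  res <- consistency_residual(mu_grid, c_obs, a_obs, spec)

  roots_mu <- numeric(0)
  exact <- which(res == 0)
  roots_mu <- c(roots_mu, mu_grid[exact])
  flips <- which(res[-1] * res[-length(res)] < 0)
  for (i in flips) {
    lo <- mu_grid[i]; hi <- mu_grid[i + 1]
    f_lo <- res[i]
    for (iter in 1:200) {
      mid <- (lo + hi) / 2
      f_mid <- consistency_residual(mid, c_obs, a_obs, spec)
      if (abs(f_mid) < tol || (hi - lo) < 1e-16) break
      if (sign(f_mid) == sign(f_lo)) { lo <- mid; f_lo <- f_mid } else hi <- mid
    }
    roots_mu <- c(roots_mu, (lo + hi) / 2)
  }
  roots_mu <- sort(unique(roots_mu))

  admissible <- purrr::map_dfr(roots_mu, function(mu) {
    x <- (a_obs - spec$p_opp * mu) / (1 - mu)
    tibble::tibble(
      x = x, mu = mu,
      residual_consistent = forward_consistent_share_unchecked(x, mu, spec) - c_obs,
      residual_cross_section =
        x * (1 - spec$p_not * mu) + (1 - x) * spec$p_opp * mu - a_obs)
  }) |>
    dplyr::filter(.data$x >= -1e-10, .data$x <= 1 + 1e-10) |>
    dplyr::mutate(x = pmin(pmax(.data$x, 0), 1)) |>
    dplyr::distinct()
  # collapse near-duplicate roots from grid + bisection
  if (nrow(admissible) > 1) {
    keep <- c(TRUE, diff(admissible$mu) > 1e-8)
    admissible <- admissible[keep, ]
  }

  if (nrow(admissible) == 0) {
    stop("no admissible (x, mu) root in the unit square; residual range [",
         format(min(res), digits = 4), ", ", format(max(res), digits = 4),
         "]", call. = FALSE)
  }

  primary <- admissible[which.min(admissible$mu), ]
  structure(list(x = primary$x, mu = primary$mu, roots = admissible,
                 unique = nrow(admissible) == 1,
                 c_obs = c_obs, a_obs = a_obs, spec = spec),
            class = "error_model_fit")
}

#' @export
print.error_model_fit <- function(x, ...) {
  cat("Random-misreport model solution (upper bound on hard-core opposition)\n")
  cat(sprintf("  observed: consistent share %.4f, mean cross-section share %.4f\n",
              x$c_obs, x$a_obs))
  cat(sprintf("  true invariant opposed fraction x  = %.4f\n", x$x))
  cat(sprintf("  random-response rate          mu = %.4f\n", x$mu))
  if (!x$unique) {
    cat("  NOTE:", nrow(x$roots),
        "admissible roots; reporting the smallest-mu root\n")
  }
  invisible(x)
}

#' @method tidy error_model_fit
#' @export
tidy.error_model_fit <- function(x, ...) {
  dplyr::mutate(x$roots, primary = .data$mu == x$mu)
}

#' @method glance error_model_fit
#' @export
glance.error_model_fit <- function(x, ...) {
  tibble::tibble(x = x$x, mu = x$mu, n_roots = nrow(x$roots),
                 unique = x$unique, c_obs = x$c_obs, a_obs = x$a_obs,
                 K = x$spec$K, m = x$spec$m, waves = x$spec$waves)
}
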