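# Who opposes, and who moves out of opposition: logistic and
# linear-probability models on standardised predictors, Tjur's
# coefficient of discrimination, and full-vs-sociodemographic model
# comparison on an identical estimation sample.

#' Standardise numeric columns to mean 0, SD 1
#'
#' Sample standard deviation (n - 1 denominator). Non-numeric columns
#' pass through untouched (they enter models as treatment-coded
#' indicators). The scaling record allows the inverse transform.
#'
#' @param data A data frame.
#' @param cols Character vector of columns to standardise; defaults to
#'   all numeric columns.
#' @return The data frame with the named columns standardised and an
#'   attribute `scaling`: tibble of column, center, scale.
#' @export
standardize_columns <- function(data, cols = NULL) {
  data <- tibble::as_tibble(data)
  if (is.null(cols)) {
    cols <- names(data)[vapply(data, is.numeric, logical(1))]
  }
  scaling <- tibble::tibble(column = cols, center = NA_real_,
                            scale = NA_real_)
  for (k in seq_along(cols)) {
    x <- data[[cols[k]]]
    if (!is.numeric(x)) {
      stop("column '", cols[k], "' is not numeric", call. = FALSE)
    }
    s <- stats::sd(x, na.rm = TRUE)
    if (!is.finite(s) || s == 0) {
      stop("column '", cols[k],
           "' has zero variance and cannot be standardised", call. = FALSE)
    }
    scaling$center[k] <- mean(x, na.rm = TRUE)
    scaling$scale[k] <- s
  }
  for (k in seq_len(nrow(scaling))) {
    col <- scaling$column[k]
    data[[col]] <- (data[[col]] - scaling$center[k]) / scaling$scale[k]
  }
  attr(data, "scaling") <- scaling
  data
}

#' Tjur's coefficient of discrimination
#'
#' The difference between the mean predicted probability among observed
#' positives and among observed negatives. An intuitive goodness-of-fit
#' measure for binary outcomes: the fraction of the true unit difference
#' between the two groups that the model captures. For a least-squares
#' linear probability model with intercept it equals the fraction of
#' variance explained exactly.
#'
#' @param predicted Numeric vector of predicted probabilities.
#' @param outcome Binary vector (0/1 or logical) of observed outcomes.
#' @return The statistic, a scalar in `[-1, 1]`.
#' @export
#' @examples
#' tjur_r2(c(0.18, 0.18, 0.03, 0.03), c(1, 1, 0, 0))  # 0.15
tjur_r2 <- function(predicted, outcome) {
  outcome <- as.numeric(outcome)
  stopifnot(length(predicted) == length(outcome),
            all(outcome %in% c(0, 1)))
  if (all(outcome == 1) || all(outcome == 0)) {
    stop("outcome contains a single class; Tjur's R2 is undefined",
         call. = FALSE)
  }
  mean(predicted[outcome == 1]) - mean(predicted[outcome == 0])
}

#' Derive a binary outcome vector from the panel
#'
#' `consistently_opposed`: 1 if the respondent's category is `opposed`
#' in every wave for the regime. `moved_opposed_to_willing`: among
#' respondents opposed at `from_wave`, 1 if willing at `to_wave`
#' (respondents not opposed at `from_wave` are excluded).
#'
#' @param panel A panel table.
#' @param outcome `"consistently_opposed"` or `"moved_opposed_to_willing"`.
#' @param regime `"voluntary"` or `"mandated"`.
#' @param from_wave,to_wave Waves used by the switching outcome
#'   (defaults 2 and 3).
#' @return A tibble with `id` and the 0/1 column `y`.
#' @export
panel_outcome <- function(panel,
                          outcome = c("consistently_opposed",
                                      "moved_opposed_to_willing"),
                          regime = c("voluntary", "mandated"),
                          from_wave = 2, to_wave = 3) {
  outcome <- match.arg(outcome)
  regime <- match.arg(regime)
  if (outcome == "consistently_opposed") {
    cls <- classify_consistency(panel, regime)
    tibble::tibble(id = cls$id,
                   y = as.integer(cls$consistency == "consistently_opposed"))
  } else {
    col <- likert_col(regime)
    panel <- validate_panel(panel)
    pair <- panel |>
      dplyr::filter(.data$wave %in% c(from_wave, to_wave)) |>
      dplyr::select("id", "wave", level = dplyr::all_of(col)) |>
      tidyr::pivot_wider(names_from = "wave", values_from = "level") |>
      dplyr::rename(from = dplyr::all_of(as.character(from_wave)),
                    to = dplyr::all_of(as.character(to_wave))) |>
      dplyr::filter(!is.na(.data$from), !is.na(.data$to)) |>
      dplyr::filter(likert_category(.data$from) == "opposed")
    tibble::tibble(id = pair$id,
                   y = as.integer(likert_category(pair$to) == "willing"))
  }
}

# Assemble the model frame: outcome + wave-1 covariates + optional
# belief changes (to_wave minus from_wave values of per-wave covariates).
build_model_frame <- function(panel, outcome, regime, predictors,
                              change_predictors = character(),
                              from_wave = 2, to_wave = 3) {
  panel <- validate_panel(panel)
  y_tab <- panel_outcome(panel, outcome, regime, from_wave, to_wave)
  base <- panel |>
    dplyr::group_by(.data$id) |>
    dplyr::slice_min(.data$wave, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select("id", dplyr::all_of(predictors))
  frame <- dplyr::inner_join(y_tab, base, by = "id")
  for (cv in change_predictors) {
    wide <- panel |>
      dplyr::filter(.data$wave %in% c(from_wave, to_wave)) |>
      dplyr::select("id", "wave", val = dplyr::all_of(cv)) |>
      tidyr::pivot_wider(names_from = "wave", values_from = "val")
    delta <- tibble::tibble(
      id = wide$id,
      x = wide[[as.character(to_wave)]] - wide[[as.character(from_wave)]])
    names(delta)[2] <- paste0("d_", cv)
    frame <- dplyr::inner_join(frame, delta, by = "id")
  }
  stats::na.omit(frame)
}

#' Fit a binary attitude model on standardised predictors
#'
#' Computes the outcome from the attitude taxonomy, standardises the
#' numeric predictors (categoricals enter as treatment-coded
#' indicators, unstandardised), and fits either a maximum-likelihood
#' logit or a least-squares linear probability model. List-wise deletion
#' on the predictor set.
#'
#' @inheritParams panel_outcome
#' @param predictors Character vector of covariate columns (measured at
#'   wave 1).
#' @param change_predictors Covariates whose `to_wave` minus `from_wave`
#'   change enters as an additional predictor (beliefs measured per
#'   wave).
#' @param estimator `"logit"` (default) or `"linear_probability"`.
#' @param conf Confidence level for Wald intervals (default 0.95).
#' @return An object of class `attitude_model`: list with the fitted
#'   `model`, `coefficients` tibble (standardised estimates with Wald
#'   CIs), `tjur_r2`, `pseudo_r2` (McFadden, logit only), `n`,
#'   `estimation_ids`, and the call's metadata.
#' @export
fit_attitude_model <- function(panel,
                               outcome = c("consistently_opposed",
                                           "moved_opposed_to_willing"),
                               regime = c("voluntary", "mandated"),
                               predictors,
                               change_predictors = character(),
                               estimator = c("logit", "linear_probability"),
                               from_wave = 2, to_wave = 3, conf = 0.95) {
  outcome <- match.arg(outcome)
  regime <- match.arg(regime)
  estimator <- match.arg(estimator)

  frame <- build_model_frame(panel, outcome, regime, predictors,
                             change_predictors, from_wave, to_wave)
  if (length(unique(frame$y)) < 2) {
    stop("outcome is degenerate (single class) in the estimation sample",
         call. = FALSE)
  }
  num_cols <- setdiff(
    names(frame)[vapply(frame, is.numeric, logical(1))], c("y"))
  frame_std <- standardize_columns(frame, num_cols)

  rhs <- setdiff(names(frame), c("id", "y"))
  form <- stats::as.formula(paste("y ~", paste(rhs, collapse = " + ")))
  fit <- if (estimator == "logit") {
    out <- stats::glm(form, data = frame_std, family = stats::binomial())
    if (!out$converged) {
      stop("logit failed to converge (possible separation)", call. = FALSE)
    }
    out
  } else {
    stats::lm(form, data = frame_std)
  }

  est <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  coefs <- tibble::tibble(
    term = names(est), estimate = unname(est), std_error = unname(se),
    conf_low = unname(est - z * se), conf_high = unname(est + z * se))

  p_hat <- stats::fitted(fit)
  tjur <- tjur_r2(p_hat, frame_std$y)
  pseudo <- if (estimator == "logit") {
    null_dev <- fit$null.deviance
    1 - fit$deviance / null_dev
  } else NA_real_

  structure(list(model = fit, coefficients = coefs, tjur_r2 = tjur,
                 pseudo_r2 = pseudo, n = nrow(frame_std),
                 estimation_ids = frame$id,
                 outcome = outcome, regime = regime, estimator = estimator,
                 scaling = attr(frame_std, "scaling")),
            class = "attitude_model")
}

#' @export
print.attitude_model <- function(x, ...) {
  cat("Attitude model:", x$outcome, "|", x$regime, "regime |",
      x$estimator, "| n =", x$n, "\n")
  print(x$coefficients)
  cat(sprintf("Tjur's R2 = %.4f", x$tjur_r2))
  if (!is.na(x$pseudo_r2)) cat(sprintf("  McFadden pseudo-R2 = %.4f",
                                       x$pseudo_r2))
  cat("\n")
  invisible(x)
}

#' @method tidy attitude_model
#' @export
tidy.attitude_model <- function(x, ...) x$coefficients

#' @method glance attitude_model
#' @export
glance.attitude_model <- function(x, ...) {
  tibble::tibble(tjur_r2 = x$tjur_r2, pseudo_r2 = x$pseudo_r2, n = x$n,
                 outcome = x$outcome, regime = x$regime,
                 estimator = x$estimator)
}

#' Compare full and sociodemographics-only attitude models
#'
#' Fits the full model (sociodemographics plus beliefs/attitudes) and
#' the nested sociodemographics-only model on the identical estimation
#' sample (list-wise deletion on the union of predictors), and reports
#' both Tjur's R-squared values and their difference: the explanatory
#' power of beliefs above and beyond sociodemographics.
#'
#' @inheritParams fit_attitude_model
#' @param sociodemographics Character vector of sociodemographic
#'   predictor columns.
#' @param beliefs Character vector of belief/attitude predictor columns
#'   (disjoint from `sociodemographics`).
#' @param belief_changes Belief columns whose wave-to-wave change also
#'   enters the full model.
#' @return An object of class `model_comparison`: list with `full`,
#'   `sociodemographic` (both `attitude_model`), `delta_tjur`, `n`.
#' @export
compare_attitude_models <- function(panel,
                                    outcome = c("consistently_opposed",
                                                "moved_opposed_to_willing"),
                                    regime = c("voluntary", "mandated"),
                                    sociodemographics, beliefs,
                                    belief_changes = character(),
                                    estimator = c("logit", "linear_probability"),
                                    from_wave = 2, to_wave = 3) {
  outcome <- match.arg(outcome)
  regime <- match.arg(regime)
  estimator <- match.arg(estimator)
  if (length(intersect(sociodemographics, beliefs)) > 0) {
    stop("sociodemographic and belief predictor sets must be disjoint",
         call. = FALSE)
  }

  full <- fit_attitude_model(panel, outcome, regime,
                             predictors = c(sociodemographics, beliefs),
                             change_predictors = belief_changes,
                             estimator = estimator,
                             from_wave = from_wave, to_wave = to_wave)
  # restrict to the full model's estimation sample so both fits use
  # exactly the same respondents
  panel_same <- validate_panel(panel)
  panel_same <- panel_same[panel_same$id %in% full$estimation_ids, ]
  socio <- fit_attitude_model(panel_same, outcome, regime,
                              predictors = sociodemographics,
                              estimator = estimator,
                              from_wave = from_wave, to_wave = to_wave)
  if (socio$n != full$n) {
    stop("estimation samples differ between the two models (",
         full$n, " vs ", socio$n, ")", call. = FALSE)
  }
  structure(list(full = full, sociodemographic = socio,
                 delta_tjur = full$tjur_r2 - socio$tjur_r2, n = full$n),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Model comparison (n =", x$n, ")\n")
  cat(sprintf("  full model Tjur's R2:             %.4f\n", x$full$tjur_r2))
  cat(sprintf("  sociodemographics-only Tjur's R2: %.4f\n",
              x$sociodemographic$tjur_r2))
  cat(sprintf("  difference (beliefs' added power): %.4f\n", x$delta_tjur))
  invisible(x)
}

#' @method tidy model_comparison
#' @export
tidy.model_comparison <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$full$coefficients, model = "full"),
    dplyr::mutate(x$sociodemographic$coefficients,
                  model = "sociodemographic"))
}

#' @method glance model_comparison
#' @export
glance.model_comparison <- function(x, ...) {
  tibble::tibble(tjur_full = x$full$tjur_r2,
                 tjur_sociodemographic = x$sociodemographic$tjur_r2,
                 delta_tjur = x$delta_tjur, n = x$n)
}
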