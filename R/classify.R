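# Attitude taxonomy: collapse the 0-4 Likert scale into
# opposed / undecided / willing, classify whole trajectories by
# consistency, and tabulate adjacent-wave switching.

attitude_levels <- function() c("opposed", "undecided", "willing")

consistency_levels <- function() {
  c("consistently_opposed", "consistently_undecided",
    "consistently_willing", "inconsistent")
}

#' Collapse Likert levels into attitude categories
#'
#' Levels 0 and 1 are `opposed`, level 2 `undecided`, levels 3 and 4
#' `willing`. Vectorised; missing input is an error because every caller
#' must decide its own missingness policy first.
#'
#' @param level Integer vector of Likert levels in 0--4.
#' @return A factor with levels `opposed`, `undecided`, `willing`.
#' @export
#' @examples
#' likert_category(c(0, 1, 2, 3, 4))
likert_category <- function(level) {
  if (anyNA(level)) {
    stop("missing Likert level; filter or impute before categorising",
         call. = FALSE)
  }
  if (any(level %% 1 != 0 | level < 0 | level > 4)) {
    stop("Likert level outside 0-4", call. = FALSE)
  }
  factor(attitude_levels()[findInterval(level, c(0, 2, 3)) ],
         levels = attitude_levels())
}

likert_col <- function(regime = c("voluntary", "mandated")) {
  switch(match.arg(regime), voluntary = "vol_likert", mandated = "man_likert")
}

#' Apply the vaccinated-twice policy to one regime's responses
#'
#' Respondents already vaccinated twice at a wave were not asked the
#' attitude questions, so their level is missing by construction. The two
#' policies the analyses need:
#' * `"exclude"` keeps the missing value, so complete-case filters drop
#'   the respondent (switching-table and consistency analyses);
#' * `"willing"` treats them as willing (level imputed 4), as in
#'   population-share and uptake tabulations, where the fully vaccinated
#'   count toward the willing slice.
#'
#' @param panel A panel table.
#' @param regime `"voluntary"` or `"mandated"`.
#' @param vaccinated `"exclude"` or `"willing"`.
#' @return The panel with the regime's Likert column adjusted.
#' @keywords internal
apply_vaccinated_policy <- function(panel, regime,
                                    vaccinated = c("exclude", "willing")) {
  vaccinated <- match.arg(vaccinated)
  col <- likert_col(regime)
  if (vaccinated == "willing") {
    idx <- !is.na(panel$vax_status) & panel$vax_status == "twice" &
      is.na(panel[[col]])
    panel[[col]][idx] <- 4L
  }
  panel
}

#' Per-respondent attitude trajectories and consistency classes
#'
#' Builds one row per respondent with the attitude category in each wave
#' and the consistency class: `consistently_X` when the category is `X`
#' in every wave, `inconsistent` otherwise. Only complete trajectories
#' are classified; respondents missing any wave are dropped (after the
#' vaccinated-twice policy is applied).
#'
#' @param panel A panel table.
#' @param regime `"voluntary"` or `"mandated"`.
#' @param vaccinated Policy for respondents vaccinated twice at a wave:
#'   `"exclude"` (default, they are dropped with their missing response)
#'   or `"willing"` (counted as willing).
#' @return A tibble with columns `id`, `cat_w<k>` per wave and
#'   `consistency`.
#' @export
classify_consistency <- function(panel, regime = c("voluntary", "mandated"),
                                 vaccinated = c("exclude", "willing")) {
  regime <- match.arg(regime)
  vaccinated <- match.arg(vaccinated)
  panel <- validate_panel(panel)
  panel <- apply_vaccinated_policy(panel, regime, vaccinated)
  col <- likert_col(regime)

  wide <- panel |>
    dplyr::select("id", "wave", level = dplyr::all_of(col)) |>
    tidyr::pivot_wider(names_from = "wave", values_from = "level",
                       names_prefix = "w") |>
    dplyr::filter(dplyr::if_all(dplyr::starts_with("w"), ~ !is.na(.x)))
  if (nrow(wide) == 0) {
    stop("no respondent has a complete ", regime, " trajectory", call. = FALSE)
  }

  cats <- wide |>
    dplyr::mutate(dplyr::across(dplyr::starts_with("w"), likert_category,
                                .names = "cat_{.col}")) |>
    dplyr::select("id", dplyr::starts_with("cat_"))

  cat_mat <- as.matrix(cats[, -1, drop = FALSE] |>
                         dplyr::mutate(dplyr::across(dplyr::everything(),
                                                     as.character)))
  all_same <- apply(cat_mat, 1, function(r) length(unique(r)) == 1L)
  cats$consistency <- factor(
    ifelse(all_same, paste0("consistently_", cat_mat[, 1]), "inconsistent"),
    levels = consistency_levels())
  cats
}

#' Consistency-class shares and per-wave opposition
#'
#' Shares of respondents consistently opposed, consistently undecided,
#' consistently willing, and inconsistent across all waves, together with
#' the opposed share in each wave's cross-section and the unweighted mean
#' of those per-wave shares. Shares are over the complete-trajectory
#' panel and carry their integer counts.
#'
#' @inheritParams classify_consistency
#' @return A list of class `consistency_shares`: `classes` (tibble of
#'   class, count, share), `by_wave_opposed` (tibble of wave, count, n,
#'   share), `mean_opposed` (scalar), `n` (panel size used).
#' @export
consistency_shares <- function(panel, regime = c("voluntary", "mandated"),
                               vaccinated = c("exclude", "willing")) {
  regime <- match.arg(regime)
  vaccinated <- match.arg(vaccinated)
  cls <- classify_consistency(panel, regime, vaccinated)
  n <- nrow(cls)

  classes <- cls |>
    dplyr::count(.data$consistency, name = "count", .drop = FALSE) |>
    dplyr::mutate(share = .data$count / n) |>
    dplyr::rename(class = "consistency")

  cat_cols <- grep("^cat_w", names(cls), value = TRUE)
  by_wave <- purrr::map_dfr(cat_cols, function(col) {
    tibble::tibble(
      wave = as.integer(sub("^cat_w", "", col)),
      count = sum(cls[[col]] == "opposed"),
      n = n)
  }) |>
    dplyr::mutate(share = .data$count / .data$n)

  structure(
    list(classes = classes, by_wave_opposed = by_wave,
         mean_opposed = mean(by_wave$share), n = n, regime = regime),
    class = "consistency_shares")
}

#' @export
print.consistency_shares <- function(x, ...) {
  cat("Consistency of", x$regime, "vaccination attitudes over",
      nrow(x$by_wave_opposed), "waves (n =", x$n, ")\n\n")
  print(x$classes)
  cat("\nPer-wave opposed shares:\n")
  print(x$by_wave_opposed)
  cat(sprintf("\nMean cross-section opposed share: %.4f\n", x$mean_opposed))
  invisible(x)
}

#' @method tidy consistency_shares
#' @export
tidy.consistency_shares <- function(x, ...) x$classes

#' @method glance consistency_shares
#' @export
glance.consistency_shares <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    consistently_opposed =
      x$classes$share[x$classes$class == "consistently_opposed"],
    mean_opposed = x$mean_opposed,
    n_waves = nrow(x$by_wave_opposed))
}

#' Adjacent-wave switching table
#'
#' Among respondents in a given attitude category at `from_wave`, where
#' are they at `to_wave`? Destination shares sum to one over
#' opposed / undecided / willing; the underlying counts are reported
#' alongside. Respondents vaccinated twice in either wave are excluded
#' under the default policy, matching the construction of switching
#' analyses on the unvaccinated panel.
#'
#' @param panel A panel table.
#' @param regime `"voluntary"` or `"mandated"`.
#' @param from_wave,to_wave Wave indices, both observed in the panel.
#' @param conditioned_on `"opposed"`, `"undecided"` or `"willing"`: the
#'   origin category.
#' @param vaccinated Vaccinated-twice policy, as in
#'   [classify_consistency()].
#' @return A tibble of class `switching_table` with columns
#'   `destination`, `count`, `share`, plus attributes `n_origin`,
#'   `regime`, `from_wave`, `to_wave`, `conditioned_on`.
#' @export
switching_table <- function(panel, regime = c("voluntary", "mandated"),
                            from_wave, to_wave,
                            conditioned_on = c("opposed", "undecided", "willing"),
                            vaccinated = c("exclude", "willing")) {
  regime <- match.arg(regime)
  conditioned_on <- match.arg(conditioned_on)
  vaccinated <- match.arg(vaccinated)
  panel <- validate_panel(panel)
  panel <- apply_vaccinated_policy(panel, regime, vaccinated)
  col <- likert_col(regime)

  pair <- panel |>
    dplyr::filter(.data$wave %in% c(from_wave, to_wave)) |>
    dplyr::select("id", "wave", level = dplyr::all_of(col)) |>
    tidyr::pivot_wider(names_from = "wave", values_from = "level") |>
    dplyr::rename(from = dplyr::all_of(as.character(from_wave)),
                  to = dplyr::all_of(as.character(to_wave))) |>
    dplyr::filter(!is.na(.data$from), !is.na(.data$to)) |>
    dplyr::mutate(from_cat = likert_category(.data$from),
                  to_cat = likert_category(.data$to)) |>
    dplyr::filter(.data$from_cat == conditioned_on)
  if (nrow(pair) == 0) {
    stop("no respondent is '", conditioned_on, "' in wave ", from_wave,
         call. = FALSE)
  }

  out <- pair |>
    dplyr::count(destination = .data$to_cat, name = "count", .drop = FALSE) |>
    dplyr::mutate(share = .data$count / nrow(pair))
  structure(out, class = c("switching_table", class(out)),
            n_origin = nrow(pair), regime = regime,
            from_wave = from_wave, to_wave = to_wave,
            conditioned_on = conditioned_on)
}
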