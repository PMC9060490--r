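# Crowding-out of vaccination willingness under a hypothetical mandate:
# within one wave, cross-tabulate each respondent's mandated-regime
# response against their voluntary-regime category.

#' Crowding-out cross-tabulation for one wave
#'
#' Among respondents in a given attitude category under the voluntary
#' regime at `wave`, where would they stand if vaccination were
#' mandated? Destination shares are expressed, by default, relative to
#' the full wave population, so they decompose the conditioning
#' subgroup's population share exactly (the decomposition identity holds
#' on raw counts); `normalize = "subgroup"` rescales them to sum to 1
#' within the subgroup. Respondents vaccinated twice are excluded (they
#' were not asked either attitude question).
#'
#' @param panel A panel table.
#' @param wave Wave index at which both regime responses are observed.
#' @param conditioning `"opposed"`, `"undecided"` or `"willing"`: the
#'   voluntary-regime category conditioned on.
#' @param normalize `"population"` (default; shares of the full wave
#'   population) or `"subgroup"` (shares within the conditioning set).
#' @return A tibble of class `crowding_table` with columns `destination`
#'   (mandated-regime category), `count`, `share`; attributes
#'   `conditioning`, `conditioning_share`, `n_wave`, `n_subgroup`,
#'   `net_effect` (share becoming willing minus share becoming opposed,
#'   within the subgroup).
#' @export
crowding_table <- function(panel, wave,
                           conditioning = c("opposed", "undecided", "willing"),
                           normalize = c("population", "subgroup")) {
  conditioning <- match.arg(conditioning)
  normalize <- match.arg(normalize)
  panel <- validate_panel(panel)

  w <- panel |>
    dplyr::filter(.data$wave == !!wave,
                  is.na(.data$vax_status) | .data$vax_status != "twice",
                  !is.na(.data$vol_likert), !is.na(.data$man_likert)) |>
    dplyr::mutate(vol_cat = likert_category(.data$vol_likert),
                  man_cat = likert_category(.data$man_likert))
  if (nrow(w) == 0) stop("no paired regime responses in wave ", wave,
                         call. = FALSE)
  sub <- dplyr::filter(w, .data$vol_cat == conditioning)
  if (nrow(sub) == 0) {
    stop("no respondent is '", conditioning, "' under the voluntary regime ",
         "in wave ", wave, call. = FALSE)
  }

  denom <- if (normalize == "population") nrow(w) else nrow(sub)
  out <- sub |>
    dplyr::count(destination = .data$man_cat, name = "count", .drop = FALSE) |>
    dplyr::mutate(share = .data$count / denom)

  within <- out$count / nrow(sub)
  net <- within[out$destination == "willing"] -
    within[out$destination == "opposed"]

  structure(out, class = c("crowding_table", class(out)),
            conditioning = conditioning,
            conditioning_share = nrow(sub) / nrow(w),
            n_wave = nrow(w), n_subgroup = nrow(sub),
            net_effect = net, normalize = normalize)
}

#' @export
print.crowding_table <- function(x, ...) {
  cat("Crowding-out table: voluntary-regime '", attr(x, "conditioning"),
      "' (", attr(x, "n_subgroup"), " of ", attr(x, "n_wave"),
      " respondents, share ",
      sprintf("%.3f", attr(x, "conditioning_share")),
      ") under a mandate:\n", sep = "")
  NextMethod()
  cat(sprintf("Net attitude effect (willing - opposed, within subgroup): %+.3f\n",
              attr(x, "net_effect")))
  invisible(x)
}

#' Naive uptake prediction from stated willingness
#'
#' The share of a wave's respondents who either agree with voluntary
#' vaccination (Likert level 3 or 4) or are already vaccinated twice --
#' the level vaccination coverage would approach if all the willing
#' followed through.
#'
#' @param panel A panel table.
#' @param wave Wave index.
#' @return A one-row tibble: `n`, `n_willing`, `n_vaccinated_twice`,
#'   `predicted_uptake`.
#' @export
naive_uptake_prediction <- function(panel, wave) {
  panel <- validate_panel(panel)
  w <- dplyr::filter(panel, .data$wave == !!wave)
  if (nrow(w) == 0) stop("no respondents in wave ", wave, call. = FALSE)
  twice <- !is.na(w$vax_status) & w$vax_status == "twice"
  willing <- !twice & !is.na(w$vol_likert) & w$vol_likert >= 3
  tibble::tibble(
    n = nrow(w),
    n_willing = sum(willing),
    n_vaccinated_twice = sum(twice),
    predicted_uptake = (sum(willing) + sum(twice)) / nrow(w))
}
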