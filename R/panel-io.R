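# Long-format panel tables: one row per respondent x wave, with Likert
# attitude columns for the voluntary and mandated regimes, vaccination
# status, and arbitrary covariate columns.

#' Column names every panel table must carry
#'
#' @keywords internal
panel_core_cols <- function() {
  c("id", "wave", "vol_likert", "man_likert", "vax_status")
}

#' Recognised vaccination statuses, in non-decreasing order
#' @keywords internal
vax_levels <- function() c("unvaccinated", "once", "twice")

#' Validate a long-format attitude panel
#'
#' Checks the structural contract of a panel table: required columns
#' present, Likert levels integers in 0--4 (or missing), waves positive
#' integers, at most one row per respondent and wave, vaccination status
#' one of `"unvaccinated"`, `"once"`, `"twice"` and non-decreasing over a
#' respondent's waves. Violations are reported with the offending rows.
#'
#' @param panel A data frame with columns `id`, `wave`, `vol_likert`,
#'   `man_likert`, `vax_status` and optionally covariates.
#' @return The panel as a tibble, invisibly classed `vax_panel`, with
#'   `wave` coerced to integer.
#' @export
validate_panel <- function(panel) {
  stopifnot(is.data.frame(panel))
  missing_cols <- setdiff(panel_core_cols(), names(panel))
  if (length(missing_cols) > 0) {
    stop("panel is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  panel <- tibble::as_tibble(panel)
  panel$wave <- as.integer(panel$wave)
  if (anyNA(panel$wave) || any(panel$wave < 1L)) {
    stop("wave must be a positive integer for every row", call. = FALSE)
  }

  bad_level <- function(x) !is.na(x) & (x %% 1 != 0 | x < 0 | x > 4)
  for (col in c("vol_likert", "man_likert")) {
    bad <- which(bad_level(panel[[col]]))
    if (length(bad) > 0) {
      stop("column '", col, "' has values outside the 0-4 Likert range in row(s): ",
           paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
    }
    panel[[col]] <- as.integer(panel[[col]])
  }

  bad_status <- which(!is.na(panel$vax_status) &
                        !panel$vax_status %in% vax_levels())
  if (length(bad_status) > 0) {
    stop("unknown vax_status in row(s): ",
         paste(utils::head(bad_status, 10), collapse = ", "), call. = FALSE)
  }

  dup <- duplicated(panel[, c("id", "wave")])
  if (any(dup)) {
    stop("duplicate (id, wave) pairs in row(s): ",
         paste(utils::head(which(dup), 10), collapse = ", "), call. = FALSE)
  }

  # vaccination status must never regress across waves
  rank <- match(panel$vax_status, vax_levels())
  ord <- order(panel$id, panel$wave)
  r <- rank[ord]
  same <- panel$id[ord][-1] == panel$id[ord][-nrow(panel)]
  if (nrow(panel) > 1) {
    regress <- which(same & !is.na(r[-1]) & !is.na(r[-length(r)]) &
                       r[-1] < r[-length(r)])
    if (length(regress) > 0) {
      ids <- unique(panel$id[ord][regress + 1])
      stop("vax_status decreases across waves for respondent(s): ",
           paste(utils::head(ids, 10), collapse = ", "), call. = FALSE)
    }
  }

  class(panel) <- unique(c("vax_panel", class(panel)))
  panel
}

#' Read an attitude panel from CSV
#'
#' Expects a UTF-8 CSV with a header row, one row per respondent and wave.
#' Default columns are `id`, `wave`, `vol_likert`, `man_likert`,
#' `vax_status`; any further columns are kept as covariates. A `schema`
#' map renames differently-labelled source columns onto this scheme, so
#' deposited data with its own header can be read without editing the
#' file. Missing values are empty cells (or `NA`), never sentinel codes.
#'
#' @param path Path to the CSV file.
#' @param schema Optional named character vector mapping canonical names
#'   to the column names used in the file, e.g.
#'   `c(id = "pid", vol_likert = "vac_vol")`.
#' @return A validated `vax_panel` tibble.
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_panel(toy_panel(), f)
#' read_panel(f)
read_panel <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(schema)) {
    schema <- schema[schema %in% names(raw)]
    for (canon in names(schema)) {
      names(raw)[names(raw) == schema[[canon]]] <- canon
    }
  }
  missing_cols <- setdiff(panel_core_cols(), names(raw))
  if (length(missing_cols) > 0) {
    stop("CSV at '", path, "' lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  validate_panel(raw)
}

#' Write an attitude panel to CSV
#'
#' Inverse of [read_panel()]: the written file round-trips field-for-field.
#'
#' @param panel A panel table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  panel <- validate_panel(panel)
  readr::write_csv(panel, path, progress = FALSE)
  invisible(path)
}

#' Restrict a panel to respondents observed in every wave
#'
#' List-wise deletion for a given regime: keeps only respondents whose
#' attitude response for that regime is non-missing in all waves of the
#' panel. With `regime = "either"` a respondent is kept when both regime
#' responses are complete.
#'
#' @param panel A panel table.
#' @param regime `"voluntary"`, `"mandated"` or `"either"` (both complete).
#' @param waves Integer vector of waves that must be present; defaults to
#'   all waves occurring in `panel`.
#' @return The complete-case subset, a `vax_panel` tibble.
#' @export
complete_cases <- function(panel, regime = c("voluntary", "mandated", "either"),
                           waves = NULL) {
  regime <- match.arg(regime)
  panel <- validate_panel(panel)
  if (is.null(waves)) waves <- sort(unique(panel$wave))
  cols <- switch(regime,
    voluntary = "vol_likert",
    mandated  = "man_likert",
    either    = c("vol_likert", "man_likert"))
  keep <- panel |>
    dplyr::filter(.data$wave %in% waves) |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(
      ok = dplyr::n() == length(waves) &&
        all(!is.na(dplyr::pick(dplyr::all_of(cols)))),
      .groups = "drop") |>
    dplyr::filter(.data$ok)
  out <- dplyr::semi_join(panel, keep, by = "id")
  validate_panel(out)
}

#' Subset a panel by a covariate predicate
#'
#' Filters respondents with a tidy predicate on covariate columns,
#' evaluated once per respondent on that respondent's first row, so the
#' respondent is kept or dropped whole. Columns named in the predicate
#' must exist.
#'
#' @param panel A panel table.
#' @param ... Logical predicates on covariates, as in [dplyr::filter()],
#'   e.g. `region == "East"` or `age >= 50`.
#' @return The filtered `vax_panel` tibble.
#' @export
panel_subset <- function(panel, ...) {
  panel <- validate_panel(panel)
  quos <- rlang::enquos(...)
  vars <- unlist(lapply(quos, function(q) all.vars(rlang::quo_get_expr(q))))
  unknown <- setdiff(vars, names(panel))
  if (length(unknown) > 0) {
    stop("unknown covariate(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  first_rows <- panel |>
    dplyr::group_by(.data$id) |>
    dplyr::slice_min(.data$wave, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::filter(!!!quos)
  out <- dplyr::semi_join(panel, first_rows, by = "id")
  validate_panel(out)
}

#' A tiny well-formed demonstration panel
#'
#' Three respondents, three waves, no missing data: one consistently
#' willing, one consistently opposed, one switching from opposition to
#' willingness.
#'
#' @return A `vax_panel` tibble of 9 rows.
#' @export
toy_panel <- function() {
  validate_panel(tibble::tibble(
    id = rep(c("r1", "r2", "r3"), each = 3),
    wave = rep(1:3, times = 3),
    vol_likert = c(4L, 4L, 3L, 0L, 1L, 0L, 1L, 2L, 4L),
    man_likert = c(3L, 4L, 3L, 0L, 0L, 0L, 0L, 1L, 3L),
    vax_status = c("unvaccinated", "unvaccinated", "once",
                   rep("unvaccinated", 6)),
    region = rep(c("West", "East", "West"), each = 3),
    age = rep(c(34, 61, 45), each = 3)
  ))
}
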