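# CSV schemas and panel-inclusion filters.
#
# All files are comma-separated with a header row, UTF-8, ISO-8601 dates:
#   events(physician_id, practice_id, date[, n_visits])
#   employment(physician_id, practice_id, contract, start_date, end_date)
#   registration(practice_id, month, patients)
#   attributes(practice_id, ownership, ownership_subtype, location,
#              morbidity, deprivation, open_year, close_year)

read_schema <- function(path, col_types, date_cols, what, allow_na_dates = character()) {
  x <- readr::read_csv(path, col_types = col_types, progress = FALSE)
  check_columns(x, names(col_types$cols), what)
  for (cl in date_cols) {
    bad <- which(is.na(x[[cl]]))
    if (cl %in% allow_na_dates) next
    if (length(bad) > 0) {
      abort_input(sprintf("%s (%s): missing/malformed `%s` at row(s): %s",
                          what, path, cl, paste(utils::head(bad, 10), collapse = ", ")))
    }
  }
  x
}

#' Read and write consultation events
#'
#' @param path File path.
#' @return `read_events()` returns a tibble `physician_id`, `practice_id`,
#'   `date` (plus `n_visits` when present in the file).
#' @export
read_events <- function(path) {
  hdr <- names(readr::read_csv(path, n_max = 0, col_types = readr::cols(.default = "c"),
                               progress = FALSE))
  ct <- readr::cols(physician_id = "c", practice_id = "c", date = readr::col_date())
  if ("n_visits" %in% hdr) ct$cols$n_visits <- readr::col_integer()
  read_schema(path, ct, "date", "events file")
}

#' @rdname read_events
#' @param x Data frame to write.
#' @export
write_events <- function(x, path) {
  check_columns(x, c("physician_id", "practice_id", "date"), "`x`")
  readr::write_csv(x, path)
  invisible(path)
}

#' Read and write employment records
#'
#' Open-ended employment is encoded as an empty `end_date`.
#' @inheritParams read_events
#' @export
read_employment <- function(path) {
  read_schema(path, readr::cols(physician_id = "c", practice_id = "c", contract = "c",
                                start_date = readr::col_date(),
                                end_date = readr::col_date()),
              c("start_date", "end_date"), "employment file",
              allow_na_dates = "end_date")
}

#' @rdname read_employment
#' @param x Data frame to write.
#' @export
write_employment <- function(x, path) {
  check_columns(x, c("physician_id", "practice_id", "contract", "start_date", "end_date"), "`x`")
  readr::write_csv(x, path)
  invisible(path)
}

#' Read and write monthly registration counts
#'
#' @inheritParams read_events
#' @export
read_registration <- function(path) {
  read_schema(path, readr::cols(practice_id = "c", month = readr::col_date(),
                                patients = readr::col_integer()),
              "month", "registration file")
}

#' @rdname read_registration
#' @param x Data frame to write.
#' @export
write_registration <- function(x, path) {
  check_columns(x, c("practice_id", "month", "patients"), "`x`")
  readr::write_csv(x, path)
  invisible(path)
}

#' Read and write practice attributes
#'
#' @inheritParams read_events
#' @export
read_attributes <- function(path) {
  read_schema(path, readr::cols(practice_id = "c", ownership = "c",
                                ownership_subtype = "c", location = "c",
                                morbidity = "d", deprivation = "d",
                                open_year = "i", close_year = "i"),
              character(), "attributes file")
}

#' @rdname read_attributes
#' @param x Data frame to write.
#' @export
write_attributes <- function(x, path) {
  check_columns(x, c("practice_id", "ownership", "ownership_subtype", "location",
                     "morbidity", "deprivation", "open_year", "close_year"), "`x`")
  readr::write_csv(x, path)
  invisible(path)
}

#' Define the analysis panel
#'
#' The panel runs from `start_year` to `end_year` of data, with annual turnover
#' computed through `final_turnover_year` (the final year must leave room for
#' the turnover horizon before the data end). Practices operating fewer than
#' `min_years_operating` years inside the window are excluded, and for closing
#' practices the closure year is excluded when `exclude_closure_year` is set.
#'
#' @param start_year,end_year Calendar span of the data window.
#' @param min_years_operating Minimum years of operation for inclusion.
#' @param exclude_closure_year Drop the closure year of closing practices?
#' @param final_turnover_year Last year entering the annual turnover panel.
#' @return A list of class `panel_definition`.
#' @export
panel_definition <- function(start_year = 2010, end_year = 2019,
                             min_years_operating = 2,
                             exclude_closure_year = TRUE,
                             final_turnover_year = 2018) {
  if (!is_scalar_number(start_year) || !is_scalar_number(end_year) ||
      !is_scalar_number(final_turnover_year) ||
      start_year > final_turnover_year || final_turnover_year > end_year) {
    abort_config("final_turnover_year",
                 "requires start_year <= final_turnover_year <= end_year.")
  }
  if (!is_count(min_years_operating)) {
    abort_config("min_years_operating", "must be a positive integer.")
  }
  structure(list(start_year = as.integer(start_year),
                 end_year = as.integer(end_year),
                 min_years_operating = as.integer(min_years_operating),
                 exclude_closure_year = isTRUE(exclude_closure_year),
                 final_turnover_year = as.integer(final_turnover_year)),
            class = "panel_definition")
}

#' Apply the panel-inclusion filters
#'
#' Removes practices operating fewer than the minimum number of years inside
#' the window, drops closure-year events for closing practices, restricts
#' events to the data window and reports, per included practice, its span of
#' analysis years, so that the practice-year panel (including the count of
#' practice-year observations) can be accounted for exactly.
#'
#' @param events Consultation events.
#' @param attributes Practice attribute table carrying `open_year` and
#'   `close_year` (`NA` = never closed).
#' @param panel A [panel_definition()].
#' @return A list with `events` (filtered), `attributes` (included practices),
#'   `report` (per-practice inclusion report with analysis-year spans) and
#'   `panel`. The total number of practice-year observations is in the
#'   `pcc_years` attribute of `report`.
#' @export
apply_panel_filters <- function(events, attributes, panel) {
  if (!inherits(panel, "panel_definition")) {
    abort_param("`panel` must be created by panel_definition().")
  }
  check_columns(events, c("physician_id", "practice_id", "date"), "`events`")
  check_columns(attributes, c("practice_id", "open_year", "close_year"), "`attributes`")
  ev_years <- if (nrow(events) > 0) range(year(events$date)) else
    c(panel$start_year, panel$end_year)
  if (panel$start_year > ev_years[2] || panel$end_year < ev_years[1]) {
    abort_config("panel", sprintf(
      "window [%d, %d] lies outside the event data range [%d, %d].",
      panel$start_year, panel$end_year, ev_years[1], ev_years[2]))
  }

  rep_tbl <- attributes |>
    mutate(
      first_year = pmax(.data$open_year, panel$start_year),
      op_last = pmin(if_else(is.na(.data$close_year), panel$end_year,
                             as.integer(.data$close_year)), panel$end_year),
      n_operating = .data$op_last - .data$first_year + 1L,
      last_year = pmin(
        if_else(!is.na(.data$close_year) & panel$exclude_closure_year,
                as.integer(.data$close_year) - 1L, .data$op_last),
        panel$final_turnover_year),
      n_panel_years = pmax(0L, .data$last_year - .data$first_year + 1L),
      included = .data$n_operating >= panel$min_years_operating &
        .data$n_panel_years > 0L,
      reason = dplyr::case_when(
        .data$n_operating < panel$min_years_operating ~ "below_min_years_operating",
        .data$n_panel_years <= 0L ~ "no_panel_years",
        TRUE ~ NA_character_)) |>
    select(all_of(c("practice_id", "included", "reason", "first_year",
                    "last_year", "n_operating", "n_panel_years",
                    "open_year", "close_year")))

  included <- filter(rep_tbl, .data$included)
  ev <- events |>
    mutate(.yr = year(.data$date)) |>
    filter(.data$.yr >= panel$start_year, .data$.yr <= panel$end_year) |>
    semi_join(included, by = "practice_id") |>
    left_join(select(attributes, all_of(c("practice_id", "close_year"))),
              by = "practice_id")
  if (panel$exclude_closure_year) {
    ev <- filter(ev, is.na(.data$close_year) | .data$.yr != .data$close_year)
  }
  ev <- select(ev, -all_of(c(".yr", "close_year")))

  rep_tbl <- structure(rep_tbl, pcc_years = sum(included$n_panel_years))
  list(events = ev,
       attributes = semi_join(attributes, included, by = "practice_id"),
       report = rep_tbl, panel = panel)
}

#' Practice-year grid of an inclusion report
#'
#' Expands the per-practice analysis-year spans of [apply_panel_filters()]
#' into the (practice, year) grid that defines the annual turnover panel.
#'
#' @param report The `report` element of [apply_panel_filters()].
#' @return A tibble `practice_id`, `year`.
#' @export
panel_practice_years <- function(report) {
  check_columns(report, c("practice_id", "included", "first_year", "last_year"), "`report`")
  inc <- filter(report, .data$included)
  tidyr::uncount(select(inc, all_of(c("practice_id", "first_year", "last_year"))),
                 .data$last_year - .data$first_year + 1L, .id = "k") |>
    mutate(year = .data$first_year + .data$k - 1L) |>
    select(all_of(c("practice_id", "year")))
}
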