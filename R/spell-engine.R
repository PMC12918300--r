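# Spell engine: monthly regular-workforce rosters and physician-practice
# spells from raw consultation events.
#
# The two primitives here carry the measurement model of the package:
#   * a physician belongs to a practice's *regular workforce* in a calendar
#     month when they provided consultations on at least `min_days` distinct
#     days in that practice and month (default 10; 15 and 20 are the usual
#     sensitivity thresholds);
#   * a *spell* is a maximal period of regular care provision by one physician
#     at one practice, terminated by a consultation-free gap of at least
#     `gap_days` (default 365, so leaves of up to one year do not end a spell).

#' Build monthly regular-workforce rosters
#'
#' Collapses consultation events to distinct consultation days per physician,
#' practice and calendar month, and keeps the physician-months meeting the
#' regular-workforce day threshold. Multiple consultations on the same day
#' count as a single day: the workforce definition counts days, not visits.
#'
#' @param events A data frame of consultation events with columns
#'   `physician_id`, `practice_id` and `date` (class `Date`). Extra columns
#'   (e.g. visit counts) are ignored.
#' @param min_days Minimum number of distinct consultation days in a
#'   (practice, month) for a physician to count as regular workforce.
#'   Inclusive: exactly `min_days` days qualifies.
#'
#' @return A tibble with one row per workforce member and month:
#'   `practice_id`, `month` (first day of the calendar month), `physician_id`,
#'   `n_days`. Practice-months in which no physician qualifies are absent.
#'   The threshold is recorded in the `min_days` attribute.
#' @seealso [workforce_size()], [build_spells()]
#' @export
build_workforce <- function(events, min_days = 10) {
  if (!is_count(min_days)) {
    abort_param("`min_days` must be a positive integer (got a value < 1 or non-integer).")
  }
  check_columns(events, c("physician_id", "practice_id", "date"), "`events`")
  if (nrow(events) == 0) abort_input("`events` is empty; no workforce can be built.")
  check_dates(events, "date", "`events`")

  events |>
    distinct(.data$physician_id, .data$practice_id, .data$date) |>
    mutate(month = month_first(.data$date)) |>
    count(.data$practice_id, .data$month, .data$physician_id, name = "n_days") |>
    filter(.data$n_days >= min_days) |>
    arrange(.data$practice_id, .data$month, .data$physician_id) |>
    structure(min_days = min_days)
}

#' Workforce size per practice-month
#'
#' @param workforce Output of [build_workforce()].
#' @return A tibble `practice_id`, `month`, `size`.
#' @export
workforce_size <- function(workforce) {
  check_columns(workforce, c("practice_id", "month", "physician_id"), "`workforce`")
  count(workforce, .data$practice_id, .data$month, name = "size")
}

#' Segment consultation events into physician-practice spells
#'
#' For each (physician, practice) pair, sorted distinct consultation dates are
#' split wherever the gap between consecutive dates is at least `gap_days`;
#' each segment is one spell. Spell duration is the number of days between the
#' first and the last consultation of the segment. A spell is flagged
#' `censored` when its last consultation lies within `gap_days` of the end of
#' the data window, so that its termination cannot be confirmed.
#'
#' @inheritParams build_workforce
#' @param gap_days Consultation-free gap (in days) that terminates a spell.
#'   Inclusive: a gap of exactly `gap_days` starts a new spell.
#' @param data_end Last date covered by the data window. Defaults to the
#'   latest event date. Events after `data_end` are an error.
#'
#' @return A tibble with columns `physician_id`, `practice_id`, `spell_id`,
#'   `first_date`, `last_date`, `duration_days`, `n_dates`, `censored`.
#' @export
build_spells <- function(events, gap_days = 365, data_end = NULL) {
  if (!is_count(gap_days)) abort_param("`gap_days` must be a positive integer.")
  check_columns(events, c("physician_id", "practice_id", "date"), "`events`")
  if (nrow(events) == 0) abort_input("`events` is empty; no spells can be built.")
  check_dates(events, "date", "`events`")
  data_end <- data_end %||% max(events$date)
  if (any(events$date > data_end)) {
    abort_input(sprintf("`events` contains %d event(s) after `data_end` (%s).",
                        sum(events$date > data_end), format(data_end)))
  }

  d <- events |>
    distinct(.data$physician_id, .data$practice_id, .data$date) |>
    arrange(.data$physician_id, .data$practice_id, .data$date)

  same_pair <- c(FALSE, d$physician_id[-1] == d$physician_id[-nrow(d)] &
                   d$practice_id[-1] == d$practice_id[-nrow(d)])
  gap <- c(NA_real_, as.numeric(diff(d$date)))
  new_spell <- !same_pair | (gap >= gap_days)
  d$spell_id <- cumsum(new_spell)

  d |>
    group_by(.data$physician_id, .data$practice_id, .data$spell_id) |>
    summarise(first_date = min(.data$date),
              last_date = max(.data$date),
              n_dates = n(),
              .groups = "drop") |>
    mutate(duration_days = as.integer(.data$last_date - .data$first_date),
           censored = as.numeric(data_end - .data$last_date) < gap_days) |>
    arrange(.data$practice_id, .data$physician_id, .data$first_date) |>
    structure(gap_days = gap_days, data_end = data_end)
}

#' Fraction of physicians who returned to a previous practice
#'
#' A physician "returned" when they have two or more spells at the same
#' practice, i.e. they resumed regular care provision after a gap long enough
#' to end a spell. Because spells at different practices do not interact, a
#' physician with single spells at several practices is not a returner.
#'
#' @param spells Output of [build_spells()].
#' @return A single proportion in `[0, 1]`: returners over distinct physicians.
#' @export
return_fraction <- function(spells) {
  check_columns(spells, c("physician_id", "practice_id", "spell_id"), "`spells`")
  if (nrow(spells) == 0) {
    abort_input("`spells` is empty; the return fraction is undefined.",
                class = "gpturnover_undefined_error")
  }
  returners <- spells |>
    count(.data$physician_id, .data$practice_id) |>
    filter(.data$n >= 2) |>
    distinct(.data$physician_id)
  nrow(returners) / n_distinct(spells$physician_id)
}
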