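# Turnover metrics: monthly within-horizon rates, annual and practice-level
# aggregation, the January-workforce rate for permanently employed physicians,
# and the permanent/temporary mixture decomposition.
#
# All rates are carried on the 0-100 percentage scale end to end.

#' Monthly within-horizon turnover rate
#'
#' For every practice-month with a regular workforce, the turnover rate is the
#' percentage of workforce members whose spell ends within `horizon_months`
#' calendar months:
#' \deqn{Turnover_{jm} = 100 \times \frac{\#\{members whose spell ends within h
#'   months\}}{\#\{members of practice j in month m\}}}
#' A member's spell "ends within h months" when its last consultation falls on
#' or before the last day of month `m + h`. Only months whose full horizon fits
#' inside the data window (end of month `m + h` at or before `data_end`) are
#' emitted.
#'
#' Spells whose recorded end lies within the gap threshold of `data_end` are
#' censored: their termination cannot be confirmed. `censor_policy` controls
#' how an ambiguous member (censored spell with recorded end inside the
#' horizon) enters the rate:
#' \describe{
#'   \item{`"as_ongoing"`}{counted as not having left (conservative default);}
#'   \item{`"as_ended"`}{the recorded last consultation is taken as a true
#'     spell end;}
#'   \item{`"exclude"`}{removed from both numerator and denominator.}
#' }
#' Members whose recorded end lies beyond the horizon are unambiguous and are
#' unaffected by the policy.
#'
#' @param workforce Output of [build_workforce()].
#' @param spells Output of [build_spells()] built from the same events.
#' @param horizon_months Horizon h in months; the study design uses
#'   6, 12, 18, 24, 36, 48 and 60.
#' @param data_end Last date of the data window; defaults to the latest spell
#'   end observed.
#' @param censor_policy One of `"as_ongoing"`, `"as_ended"`, `"exclude"`.
#'
#' @return A tibble `practice_id`, `month`, `horizon_months`, `rate`,
#'   `n_workforce`. Rates are in `[0, 100]`.
#' @export
monthly_turnover <- function(workforce, spells, horizon_months = 12,
                             data_end = NULL,
                             censor_policy = c("as_ongoing", "as_ended", "exclude")) {
  censor_policy <- match.arg(censor_policy)
  if (!is_count(horizon_months)) abort_param("`horizon_months` must be a positive integer.")
  check_columns(workforce, c("practice_id", "month", "physician_id"), "`workforce`")
  check_columns(spells, c("physician_id", "practice_id", "first_date",
                          "last_date", "censored"), "`spells`")
  data_end <- data_end %||% attr(spells, "data_end") %||% max(spells$last_date)

  j <- workforce |>
    select(all_of(c("practice_id", "month", "physician_id"))) |>
    inner_join(
      select(spells, all_of(c("physician_id", "practice_id", "first_date",
                              "last_date", "censored"))),
      by = c("physician_id", "practice_id"),
      relationship = "many-to-many"
    ) |>
    filter(.data$first_date <= month_last(.data$month),
           .data$last_date >= .data$month)

  if (nrow(j) != nrow(workforce)) {
    abort(sprintf(paste(
      "Internal consistency error: %d workforce member-month(s) do not map to",
      "exactly one covering spell. Workforce and spells must be built from the",
      "same events."), abs(nrow(workforce) - nrow(j))),
      class = "gpturnover_consistency_error")
  }

  j <- j |>
    mutate(horizon_end = month_last(add_months(.data$month, horizon_months)),
           ended_obs = .data$last_date <= .data$horizon_end) |>
    filter(.data$horizon_end <= data_end)

  j <- switch(censor_policy,
    as_ongoing = mutate(j, ended = .data$ended_obs & !.data$censored),
    as_ended = mutate(j, ended = .data$ended_obs),
    exclude = j |>
      filter(!(.data$censored & .data$ended_obs)) |>
      mutate(ended = .data$ended_obs)
  )

  j |>
    group_by(.data$practice_id, .data$month) |>
    summarise(rate = 100 * mean(.data$ended), n_workforce = n(), .groups = "drop") |>
    mutate(horizon_months = as.integer(horizon_months)) |>
    relocate(all_of(c("practice_id", "month", "horizon_months", "rate", "n_workforce"))) |>
    structure(censor_policy = censor_policy)
}

#' Annual turnover rate per practice
#'
#' Aggregates monthly rates to the practice-year level by averaging over the
#' *defined* months of each practice and year (months with no regular
#' workforce contribute nothing). Practice-years listed in `practice_years`
#' but having zero defined months are emitted with `rate = NA` and
#' `n_months_defined = 0`; they are the "no regular workforce" observations
#' that [impute_missing()] fills in.
#'
#' @param monthly Output of [monthly_turnover()] at a single horizon.
#' @param practice_years Optional tibble (`practice_id`, `year`) giving the
#'   full analysis panel, so that missing practice-years can be emitted.
#'   Defaults to the practice-years present in `monthly`.
#'
#' @return A tibble `practice_id`, `year`, `rate`, `n_months_defined`,
#'   `imputed` (all `FALSE` here).
#' @export
annual_turnover <- function(monthly, practice_years = NULL) {
  check_columns(monthly, c("practice_id", "month", "horizon_months", "rate"),
                "`monthly`")
  if (length(unique(monthly$horizon_months)) > 1) {
    abort_param("`monthly` mixes several horizons; aggregate one horizon at a time.")
  }

  ann <- monthly |>
    mutate(year = year(.data$month)) |>
    group_by(.data$practice_id, .data$year) |>
    summarise(rate = mean(.data$rate), n_months_defined = n(), .groups = "drop")

  if (!is.null(practice_years)) {
    check_columns(practice_years, c("practice_id", "year"), "`practice_years`")
    ann <- practice_years |>
      distinct(.data$practice_id, .data$year) |>
      left_join(ann, by = c("practice_id", "year")) |>
      mutate(n_months_defined = if_else(is.na(.data$n_months_defined), 0L,
                                        .data$n_months_defined))
  }

  ann |>
    mutate(imputed = FALSE) |>
    arrange(.data$practice_id, .data$year)
}

#' Impute practice-years with no regular workforce
#'
#' A practice-year with zero defined months receives the mean of that
#' practice's observed annual rates. The number of imputations performed is
#' recorded in the `n_imputed` attribute.
#'
#' @param annual Output of [annual_turnover()].
#' @param on_all_missing What to do with practices whose every year is
#'   missing: `"error"` (default) aborts listing the practices; `"drop"`
#'   removes them (their ids are recorded in the `dropped_practices`
#'   attribute).
#' @return `annual` with missing rates filled in and `imputed = TRUE` on the
#'   filled rows.
#' @export
impute_missing <- function(annual, on_all_missing = c("error", "drop")) {
  on_all_missing <- match.arg(on_all_missing)
  check_columns(annual, c("practice_id", "year", "rate"), "`annual`")

  all_missing <- annual |>
    group_by(.data$practice_id) |>
    summarise(none = all(is.na(.data$rate)), .groups = "drop") |>
    filter(.data$none) |>
    pull("practice_id")
  if (length(all_missing) > 0) {
    if (on_all_missing == "error") {
      abort(sprintf("Imputation impossible: practice(s) with no observed year: %s",
                    paste(all_missing, collapse = ", ")),
            class = "gpturnover_imputation_error",
            practices = all_missing)
    }
    annual <- filter(annual, !.data$practice_id %in% all_missing)
  }

  out <- annual |>
    group_by(.data$practice_id) |>
    mutate(pcc_mean = mean(.data$rate, na.rm = TRUE)) |>
    ungroup() |>
    mutate(imputed = is.na(.data$rate),
           rate = if_else(is.na(.data$rate), .data$pcc_mean, .data$rate)) |>
    select(-"pcc_mean")

  structure(out, n_imputed = sum(out$imputed),
            dropped_practices = all_missing)
}

#' Time-invariant practice-level turnover
#'
#' The practice-level measure is the unweighted mean of the practice's annual
#' rates over its years in the panel.
#'
#' @param annual Output of [annual_turnover()], normally after
#'   [impute_missing()].
#' @return A tibble `practice_id`, `rate`, `n_years`.
#' @export
practice_average <- function(annual) {
  check_columns(annual, c("practice_id", "year", "rate"), "`annual`")
  if (anyNA(annual$rate)) {
    warn("`annual` still contains missing rates; run impute_missing() first. Practice means will be NA.")
  }
  annual |>
    group_by(.data$practice_id) |>
    summarise(rate = mean(.data$rate), n_years = n(), .groups = "drop")
}

#' Annual turnover of permanently employed physicians
#'
#' When only employment records (not consultations) identify permanent staff,
#' turnover is measured against the January workforce: the denominator is the
#' set of physicians on a qualifying contract employed at the practice on 31
#' January, the numerator those of them whose employment ends during that
#' calendar year. Hires after 31 January are excluded from both, keeping the
#' rate at or below 100.
#'
#' @param employment Data frame with `physician_id`, `practice_id`, `contract`,
#'   `start_date`, `end_date` (`NA` end = still employed).
#' @param years Calendar years to evaluate.
#' @param contracts Contract type(s) forming the population, usually
#'   `"permanent"` or `"registrar"`.
#' @return A tibble `practice_id`, `year`, `rate`, `n_january`, one row per
#'   practice-year with at least one January employee.
#' @export
permanent_turnover <- function(employment, years, contracts = "permanent") {
  check_columns(employment,
                c("physician_id", "practice_id", "contract", "start_date", "end_date"),
                "`employment`")
  if (length(years) == 0 || !all(years == as.integer(years))) {
    abort_param("`years` must be one or more calendar years.")
  }
  yr_min <- min(year(employment$start_date), na.rm = TRUE)
  yr_max <- if (anyNA(employment$end_date)) Inf else
    max(year(employment$end_date), year(employment$start_date), na.rm = TRUE)
  if (any(years < yr_min | years > yr_max)) {
    abort_param(sprintf("`years` outside the employment-data window [%s, %s].",
                        yr_min, ifelse(is.finite(yr_max), yr_max, "open")))
  }

  emp <- filter(employment, .data$contract %in% contracts)
  out <- lapply(sort(unique(as.integer(years))), function(y) {
    jan31 <- as.Date(sprintf("%d-01-31", y))
    den <- emp |>
      filter(.data$start_date <= jan31,
             is.na(.data$end_date) | .data$end_date >= jan31)
    if (nrow(den) == 0) return(NULL)
    den |>
      mutate(quit = !is.na(.data$end_date) & year(.data$end_date) == y) |>
      group_by(.data$practice_id) |>
      summarise(n_january = n_distinct(.data$physician_id),
                n_quit = n_distinct(.data$physician_id[.data$quit]),
                .groups = "drop") |>
      mutate(year = y, rate = 100 * .data$n_quit / .data$n_january)
  })
  out <- bind_rows(out)
  if (nrow(out) == 0) {
    return(tibble(practice_id = character(), year = integer(),
                  rate = numeric(), n_january = integer()))
  }
  out |>
    select(all_of(c("practice_id", "year", "rate", "n_january"))) |>
    arrange(.data$practice_id, .data$year)
}

#' Temporary-staff share implied by a turnover mixture
#'
#' Treats the overall turnover rate as a two-component mixture of permanent
#' staff (turning over at `permanent_rate`) and temporary staff (whose spells
#' end within the horizon with probability `temporary_exit_prob`), and solves
#' \deqn{overall = (1 - s) \cdot permanent + s \cdot temporary} for the
#' temporary share `s`.
#'
#' @param overall_rate,permanent_rate Rates on the 0-100 scale.
#' @param temporary_exit_prob Within-horizon exit probability of temporary
#'   staff, on the 0-100 scale; 100 by default (short contracts essentially
#'   always end within a year).
#' @return The implied temporary share, a proportion in `[0, 1]`.
#' @export
mixture_share <- function(overall_rate, permanent_rate, temporary_exit_prob = 100) {
  for (nm in c("overall_rate", "permanent_rate", "temporary_exit_prob")) {
    if (!is_scalar_number(get(nm))) abort_param(sprintf("`%s` must be a single number.", nm))
  }
  if (permanent_rate >= temporary_exit_prob) {
    abort_param("`permanent_rate` must be below `temporary_exit_prob`.")
  }
  if (overall_rate < permanent_rate || overall_rate > temporary_exit_prob) {
    abort(sprintf(
      "Infeasible mixture: `overall_rate` (%s) must lie in [%s, %s].",
      overall_rate, permanent_rate, temporary_exit_prob),
      class = "gpturnover_domain_error")
  }
  (overall_rate - permanent_rate) / (temporary_exit_prob - permanent_rate)
}
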