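# Practice covariates: size, case-mix, deprivation, ownership, location and
# workload, with tercile / missing coding.

#' Registered patients per workforce physician
#'
#' Workload is the monthly ratio of registered patients to regular-workforce
#' size, averaged to practice level over the months in which the practice has
#' a regular workforce. Months without a workforce are skipped (there is never
#' a division by zero); a practice with no defined month has missing workload.
#'
#' @param registration Data frame `practice_id`, `month` (first-of-month
#'   `Date`), `patients`.
#' @param workforce Output of [build_workforce()].
#' @return A tibble `practice_id`, `workload`, `n_months` (months entering the
#'   average).
#' @export
compute_workload <- function(registration, workforce) {
  check_columns(registration, c("practice_id", "month", "patients"), "`registration`")
  check_columns(workforce, c("practice_id", "month", "physician_id"), "`workforce`")

  workforce_size(workforce) |>
    inner_join(registration, by = c("practice_id", "month")) |>
    mutate(ratio = .data$patients / .data$size) |>
    group_by(.data$practice_id) |>
    summarise(workload = mean(.data$ratio), n_months = n(), .groups = "drop")
}

#' Tercile coding with a missing category
#'
#' Codes a continuous practice-level measure into terciles of its distribution:
#' 1 = lowest, 2 = mid, 3 = highest tercile, 0 = missing value. Cut points are
#' rank-based (empirical CDF) with tied values assigned to the lower tercile,
#' so the coding is reproducible across software; when values are distinct the
#' three groups differ in size by at most one.
#'
#' @param values Numeric vector, one value per practice; `NA` = missing.
#' @return Integer codes in `{0, 1, 2, 3}` of the same length.
#' @export
tercile_code <- function(values) {
  if (!is.numeric(values)) abort_param("`values` must be numeric.")
  obs <- !is.na(values)
  if (!any(obs)) {
    abort_input("All values are missing; tercile coding is impossible.",
                class = "gpturnover_coding_error")
  }
  if (sum(obs) < 3) {
    abort_input("At least 3 non-missing values are required for tercile coding.",
                class = "gpturnover_coding_error")
  }
  n <- sum(obs)
  r <- rank(values[obs], ties.method = "min")
  code <- 1L + (r > ceiling(n / 3)) + (r > ceiling(2 * n / 3))
  out <- integer(length(values))
  out[obs] <- code
  out
}

#' Assemble practice profiles
#'
#' Builds one covariate profile per practice in the attribute table: raw size,
#' case-mix (morbidity), deprivation and workload values, ownership (public /
#' private), ownership subtype, location class, and the tercile / missing
#' codes used in the regression analyses. Practices with incomplete inputs are
#' listed in the `completeness` attribute and coded 0 (missing) where the
#' coding scheme allows; workload has no missing category, so practices
#' without a computable workload get `workload_code = NA` and are reported.
#'
#' @param attributes Data frame `practice_id`, `ownership_subtype`, `location`,
#'   `morbidity`, `deprivation` (an `ownership` column is derived from the
#'   subtype when absent).
#' @param registration Monthly registration counts, see [compute_workload()].
#' @param workforce Output of [build_workforce()].
#' @return A tibble of practice profiles, one row per practice.
#' @export
build_profiles <- function(attributes, registration, workforce) {
  check_columns(attributes, c("practice_id", "ownership_subtype", "location",
                              "morbidity", "deprivation"), "`attributes`")
  if (!"ownership" %in% names(attributes)) {
    attributes <- mutate(attributes, ownership = if_else(
      .data$ownership_subtype == "public", "public", "private"))
  }

  size_tbl <- registration |>
    group_by(.data$practice_id) |>
    summarise(size_patients = mean(.data$patients), .groups = "drop")
  wl <- compute_workload(registration, workforce)

  profiles <- attributes |>
    select(all_of(c("practice_id", "ownership", "ownership_subtype", "location",
                    "morbidity", "deprivation"))) |>
    left_join(size_tbl, by = "practice_id") |>
    left_join(select(wl, all_of(c("practice_id", "workload"))), by = "practice_id") |>
    mutate(size_code = tercile_code(.data$size_patients),
           morbidity_code = tercile_code(.data$morbidity),
           deprivation_code = tercile_code(.data$deprivation),
           workload_code = {
             wc <- tercile_code(.data$workload)
             ifelse(wc == 0L, NA_integer_, wc)
           })

  report <- bind_rows(
    tibble(practice_id = setdiff(unique(c(registration$practice_id,
                                          workforce$practice_id)),
                                 attributes$practice_id),
           issue = "missing_attributes"),
    tibble(practice_id = profiles$practice_id[is.na(profiles$size_patients)],
           issue = "no_registration_data"),
    tibble(practice_id = profiles$practice_id[is.na(profiles$workload)],
           issue = "no_workload")
  )
  structure(profiles, completeness = report)
}
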