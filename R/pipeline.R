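# End-to-end analysis pipeline.

#' Run the full turnover analysis
#'
#' Ties the stages together: (optionally) simulate a registry, apply the
#' panel-inclusion filters, build spells over the full data window and monthly
#' workforce rosters, compute monthly/annual/practice-level turnover with
#' imputation of practice-years lacking a regular workforce, assemble practice
#' profiles, and produce bivariate summaries and the regression fits. The run
#' is deterministic given inputs and seed; a manifest records parameters and
#' record counts at every stage.
#'
#' @param registry A `synthetic_registry` or a list with `events`,
#'   `employment`, `registration`, `attributes` tibbles (e.g. read from CSV).
#'   When `NULL`, `config` must be supplied and a registry is simulated.
#' @param config A [registry_config()], used when `registry` is `NULL`.
#' @param panel A [panel_definition()].
#' @param min_days Regular-workforce day threshold (10; 15/20 for sensitivity).
#' @param gap_days Spell-terminating gap, days.
#' @param horizon Turnover horizon in months.
#' @param censor_policy Passed to [monthly_turnover()].
#' @param balanced Restrict to the balanced panel (practices observed in every
#'   year) as a sensitivity analysis?
#' @param specifications Regression specifications to fit; `NULL` to skip.
#' @param output_dir If non-`NULL`, write every artifact (CSV files, a
#'   regression report, `manifest.json`) into this directory.
#'
#' @return A list of class `turnover_pipeline` with elements `workforce`,
#'   `spells`, `monthly`, `annual`, `practice`, `profiles`, `bivariate`,
#'   `fits`, `report`, `manifest`.
#' @export
run_pipeline <- function(registry = NULL, config = NULL,
                         panel = panel_definition(),
                         min_days = 10, gap_days = 365, horizon = 12,
                         censor_policy = "as_ongoing", balanced = FALSE,
                         specifications = c("full", "excl_private", "excl_workload"),
                         output_dir = NULL) {
  if (is.null(registry)) {
    if (is.null(config)) abort_param("Supply either `registry` or `config`.")
    registry <- with_stage("simulate", generate_registry(config))
  }
  for (el in c("events", "employment", "registration", "attributes")) {
    if (is.null(registry[[el]])) abort_input(sprintf("`registry` lacks `%s`.", el))
  }

  filt <- with_stage("panel_filters",
                     apply_panel_filters(registry$events, registry$attributes, panel))
  data_end <- if (nrow(registry$events) > 0) {
    month_last(max(registry$events$date))
  } else {
    as.Date(sprintf("%d-12-31", panel$end_year))
  }

  # spells over the full data window; the panel filters govern only which
  # practice-years enter the annual panel
  spells <- with_stage("spells", build_spells(registry$events, gap_days, data_end))
  workforce <- with_stage("workforce", build_workforce(filt$events, min_days))

  monthly <- with_stage("monthly_turnover",
                        monthly_turnover(workforce, spells, horizon, data_end,
                                         censor_policy))
  grid <- panel_practice_years(filt$report)
  annual <- with_stage("annual_turnover", annual_turnover(
    filter(monthly, year(.data$month) >= panel$start_year,
           year(.data$month) <= panel$final_turnover_year),
    practice_years = grid))
  annual <- with_stage("impute_missing", impute_missing(annual, on_all_missing = "drop"))
  n_imputed <- attr(annual, "n_imputed")
  dropped <- attr(annual, "dropped_practices")
  if (balanced) {
    annual <- with_stage("balanced_panel", balanced_panel_filter(
      annual, panel$start_year:panel$final_turnover_year))
  }
  practice <- with_stage("practice_average", practice_average(annual))

  wf_panel <- filter(workforce, year(.data$month) <= panel$final_turnover_year)
  profiles <- with_stage("profiles", build_profiles(
    semi_join(filt$attributes, practice, by = "practice_id"),
    semi_join(registry$registration, practice, by = "practice_id"),
    semi_join(wf_panel, practice, by = "practice_id")))
  bivariate <- with_stage("bivariate", bivariate_summary(practice, profiles))
  fits <- lapply(specifications, function(sp) {
    with_stage(paste0("regression_", sp),
               fit_turnover_regression(practice, profiles, sp))
  })
  names(fits) <- specifications

  manifest <- list(
    parameters = list(
      panel = unclass(panel), min_days = min_days, gap_days = gap_days,
      horizon = horizon, censor_policy = censor_policy, balanced = balanced,
      seed = if (!is.null(registry$config)) registry$config$seed,
      specifications = as.list(specifications)),
    counts = list(
      n_events_raw = nrow(registry$events),
      n_events_panel = nrow(filt$events),
      n_practices_raw = nrow(registry$attributes),
      n_practices_panel = nrow(practice),
      pcc_years = attr(filt$report, "pcc_years"),
      n_imputed_pcc_years = n_imputed,
      n_practices_dropped_all_missing = length(dropped),
      n_spells = nrow(spells),
      n_physicians = n_distinct(spells$physician_id)),
    package_version = as.character(utils::packageVersion("gpturnover")))

  out <- structure(list(workforce = workforce, spells = spells,
                        monthly = monthly, annual = annual,
                        practice = practice, profiles = profiles,
                        bivariate = bivariate, fits = fits,
                        report = filt$report, manifest = manifest),
                   class = "turnover_pipeline")
  if (!is.null(output_dir)) write_pipeline_outputs(out, output_dir)
  out
}

# write every artifact of a pipeline run as plain text; reruns with unchanged
# inputs are byte-identical
write_pipeline_outputs <- function(x, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  readr::write_csv(x$workforce, p("workforce.csv"))
  readr::write_csv(x$spells, p("spells.csv"))
  readr::write_csv(x$monthly, p("monthly_turnover.csv"))
  readr::write_csv(x$annual, p("annual_turnover.csv"))
  readr::write_csv(x$practice, p("practice_turnover.csv"))
  readr::write_csv(x$profiles, p("profiles.csv"))
  bv <- mutate(x$bivariate,
               outliers = vapply(.data$outliers, function(v)
                 paste(format(v, trim = TRUE), collapse = ";"), character(1)))
  readr::write_csv(bv, p("bivariate_summary.csv"))
  rpt <- utils::capture.output(for (f in x$fits) {
    print(f); cat("\n")
  })
  writeLines(rpt, p("regression_report.txt"))
  manifest <- x$manifest
  manifest$files <- list.files(dir)
  manifest$files <- manifest$files[manifest$files != "manifest.json"]
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @export
print.turnover_pipeline <- function(x, ...) {
  cn <- x$manifest$counts
  cat(sprintf(paste0(
    "Turnover analysis pipeline\n",
    "  practices in panel: %d (%d practice-years, %d imputed)\n",
    "  spells: %d, physicians: %d\n",
    "  mean annual turnover: %.1f%%, median practice-level: %.1f%%\n"),
    cn$n_practices_panel, cn$pcc_years, cn$n_imputed_pcc_years,
    cn$n_spells, cn$n_physicians,
    mean(x$annual$rate), stats::median(x$practice$rate)))
  invisible(x)
}

#' Boxplots of turnover by covariate level
#'
#' Renders the bivariate adjacent-value summaries with ggplot2 (suggested
#' dependency).
#'
#' @param bivariate Output of [bivariate_summary()].
#' @param covariates Covariates to show; default all.
#' @return A ggplot object.
#' @export
plot_turnover_boxplots <- function(bivariate, covariates = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    abort_param("Package `ggplot2` is required for plotting.")
  }
  d <- bivariate
  if (!is.null(covariates)) d <- filter(d, .data$covariate %in% covariates)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group)) +
    ggplot2::geom_boxplot(ggplot2::aes(
      ymin = .data$lower_adjacent, lower = .data$p25, middle = .data$median,
      upper = .data$p75, ymax = .data$upper_adjacent), stat = "identity") +
    ggplot2::facet_wrap(~covariate, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "Annual turnover (%)")
}
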