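small_cfg <- function(...) {
  registry_config(n_practices = 8, years = c(2012, 2015), seed = 99, ...)
}

test_that("generation is deterministic given config and seed", {
  r1 <- generate_registry(small_cfg())
  r2 <- generate_registry(small_cfg())
  expect_identical(r1$events, r2$events)
  expect_identical(r1$employment, r2$employment)
  expect_identical(r1$registration, r2$registration)
  expect_identical(r1$attributes, r2$attributes)
})

test_that("per-practice substreams: adding practices does not perturb existing ones", {
  r8 <- generate_registry(small_cfg())
  r12 <- generate_registry(registry_config(n_practices = 12, years = c(2012, 2015), seed = 99))
  first8 <- sprintf("pcc%04d", 1:8)
  expect_identical(r8$events,
                   dplyr::filter(r12$events, practice_id %in% first8))
  expect_identical(r8$attributes,
                   dplyr::filter(r12$attributes, practice_id %in% first8))
})

test_that("with no exits, openings or closures every physician has one panel-spanning spell", {
  cfg <- small_cfg(
    temporary_share = 0,
    exit_hazard_by_contract = c(permanent = 0, fixed_term = 0.25, freelance = 0.25,
                                registrar = 1 / 60, foundation = 1 / 6),
    p_open_close = c(open = 0, close = 0), leave_prob = 0)
  reg <- generate_registry(cfg)
  sp <- build_spells(reg$events, data_end = as.Date("2015-12-31"))
  expect_equal(nrow(sp), dplyr::n_distinct(reg$events$physician_id))
  expect_true(all(sp$first_date < as.Date("2012-02-01")))
  expect_true(all(sp$last_date > as.Date("2015-11-30")))
  expect_true(all(is.na(reg$employment$end_date)))
  expect_equal(nrow(reg$employment), nrow(sp))
})

test_that("event dates lie within their employment record", {
  reg <- generate_registry(small_cfg())
  j <- dplyr::left_join(reg$events, reg$employment,
                        by = c("physician_id", "practice_id"))
  expect_true(all(j$date >= j$start_date))
  expect_true(all(j$date <= j$end_date | is.na(j$end_date)))
  expect_true(all(j$date <= as.Date("2015-12-31")))
  # employment records are internally consistent
  emp <- reg$employment
  expect_true(all(emp$start_date <= emp$end_date | is.na(emp$end_date)))
})

test_that("invalid configurations fail naming the offending field", {
  expect_error(registry_config(n_practices = 0), "n_practices",
               class = "gpturnover_config_error")
  expect_error(registry_config(location_probs = c(city = 0.5, commuting = 0.2,
                                                  town = 0.2, rural = 0.2)),
               "location_probs", class = "gpturnover_config_error")
  expect_error(registry_config(temporary_share = 1), "temporary_share",
               class = "gpturnover_config_error")
  expect_error(registry_config(leave_max_days = 400), "leave_max_days",
               class = "gpturnover_config_error")
  expect_error(registry_config(exit_hazard_by_contract = c(
    permanent = 0.01, fixed_term = 0, freelance = 0.2, registrar = 0.02,
    foundation = 0.2)), "exit_hazard", class = "gpturnover_config_error")
  expect_error(registry_config(share_private = 0.30), "ownership_subtype_probs",
               class = "gpturnover_config_error")
})

test_that("zero-variance scores collapse to 1 and effects default to zero", {
  cfg <- small_cfg(morbidity_sd = 0)
  reg <- generate_registry(cfg)
  expect_true(all(reg$attributes$morbidity == 1))
  truth <- generate_covariate_panel(cfg, reg$attributes)
  expect_true(all(truth$hazard_shift == 0))
  expect_true(all(truth$exit_hazard_permanent == cfg$exit_hazard_by_contract[["permanent"]]))
  expect_true(all(truth$morbidity_tercile == 1L))
})

test_that("consultation-day volumes straddle the workforce thresholds and visits match the target IQR", {
  reg <- generate_registry(registry_config(n_practices = 40, years = c(2013, 2015), seed = 5))
  days <- reg$events |>
    dplyr::distinct(physician_id, practice_id, date) |>
    dplyr::mutate(month = lubridate::floor_date(date, "month")) |>
    dplyr::count(physician_id, practice_id, month)
  expect_gt(mean(days$n >= 10), 0.5)   # most active months qualify at 10 days
  expect_gt(mean(days$n < 10), 0.02)   # but some months fall below 10
  expect_gt(mean(days$n >= 20), 0.02)  # and some reach 20
  s10 <- mean(workforce_size(build_workforce(reg$events, 10))$size)
  s15 <- mean(workforce_size(build_workforce(reg$events, 15))$size)
  s20 <- mean(workforce_size(build_workforce(reg$events, 20))$size)
  expect_gt(s10, s15); expect_gt(s15, s20)
  expect_gt(s10, 4.5); expect_lt(s10, 7.5)

  daily <- dplyr::count(reg$events, practice_id, date, physician_id,
                        wt = n_visits, name = "visits")
  expect_equal(unname(quantile(daily$visits, c(.25, .75))), c(6, 8))
})

test_that("temporary share of the workforce tracks the configured target", {
  reg <- generate_registry(registry_config(n_practices = 60, years = c(2012, 2016),
                                           seed = 13))
  wf <- build_workforce(reg$events, 10)
  contract <- dplyr::distinct(reg$employment, physician_id, contract)
  share <- wf |>
    dplyr::left_join(contract, by = "physician_id") |>
    dplyr::summarise(s = mean(contract != "permanent")) |>
    dplyr::pull(s)
  expect_gt(share, 0.15); expect_lt(share, 0.25)
})

test_that("practices opening mid-panel with a long ramp-up yield exactly their first year imputed", {
  cfg <- registry_config(n_practices = 40, years = c(2010, 2016), seed = 21,
                         p_open_close = c(open = 0.5, close = 0),
                         ramp_up_months = 12)
  reg <- generate_registry(cfg)
  wf <- build_workforce(reg$events, 10)
  sp <- build_spells(reg$events, data_end = as.Date("2016-12-31"))
  mt <- monthly_turnover(wf, sp, 12, as.Date("2016-12-31"))
  panel <- panel_definition(2010, 2016, min_years_operating = 2,
                            final_turnover_year = 2015)
  filt <- apply_panel_filters(reg$events, reg$attributes, panel)
  grid <- panel_practice_years(filt$report)
  ann <- annual_turnover(
    dplyr::filter(mt, lubridate::year(month) <= 2015), practice_years = grid)
  imp <- impute_missing(ann, on_all_missing = "drop")

  # brute-force expectation: each included late opener has its opening year
  # (fully covered by the 12-month ramp) with no regular workforce
  late <- dplyr::filter(filt$report, included, open_year > 2010,
                        open_year <= 2015)
  got <- dplyr::filter(imp, imputed)
  expect_equal(sort(got$practice_id),
               sort(dplyr::filter(late, practice_id %in% imp$practice_id)$practice_id))
  expect_true(all(got$year == late$open_year[match(got$practice_id, late$practice_id)]))
})

test_that("a known deprivation effect on the exit hazard is recovered by the full pipeline", {
  q <- 0.0134; delta <- 0.01
  cfg <- registry_config(
    n_practices = 500, years = c(2012, 2017), seed = 33,
    temporary_share = 0, p_open_close = c(open = 0, close = 0),
    leave_prob = 0, ramp_up_months = 0,
    exit_hazard_by_contract = c(permanent = q, fixed_term = 0.25, freelance = 0.25,
                                registrar = 1 / 60, foundation = 1 / 6),
    covariate_effects = c(deprivation = delta))
  reg <- generate_registry(cfg)
  wf <- build_workforce(reg$events, 10)
  sp <- build_spells(reg$events, data_end = as.Date("2017-12-31"))
  mt <- monthly_turnover(wf, sp, 12, as.Date("2017-12-31")) |>
    dplyr::filter(lubridate::year(month) <= 2015)
  turn <- practice_average(annual_turnover(mt))
  prof <- build_profiles(reg$attributes, reg$registration, wf)
  fit <- fit_turnover_regression(turn, prof, "full")
  co <- fit$coefficients

  # analytic truth: two tercile steps of delta on the monthly hazard
  truth <- 100 * ((1 - (1 - q - 2 * delta)^12) - (1 - (1 - q)^12))
  est <- co$estimate[co$term == "deprivation_most_deprived"]
  se <- co$se_robust[co$term == "deprivation_most_deprived"]
  expect_lt(abs(est - truth), 2 * se)
  expect_gt(est, 0)

  # bivariate medians rise across deprivation terciles
  bs <- bivariate_summary(turn, prof)
  dep <- dplyr::filter(bs, covariate == "deprivation") |>
    dplyr::arrange(group)
  expect_true(all(diff(dep$median) > 0))

  # null covariates stay null: morbidity coefficients within 2 robust SEs of 0
  morb <- dplyr::filter(co, grepl("^morbidity", term))
  expect_true(all(abs(morb$estimate) < 2.5 * morb$se_robust))
})
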