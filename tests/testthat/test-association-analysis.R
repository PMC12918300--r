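# profile tables with known structure for regression tests
synth_profiles <- function(n, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    practice_id = sprintf("P%03d", seq_len(n)),
    ownership = sample(c("public", "private"), n, TRUE),
    ownership_subtype = "public",
    location = sample(c("city", "commuting", "town", "rural"), n, TRUE),
    morbidity = rnorm(n, 1, 0.1), deprivation = rnorm(n, 1, 0.3),
    size_patients = rnorm(n, 8000, 3000), workload = rnorm(n, 1500, 400)
  ) |>
    dplyr::mutate(size_code = tercile_code(size_patients),
                  morbidity_code = tercile_code(morbidity),
                  deprivation_code = tercile_code(deprivation),
                  workload_code = tercile_code(workload))
}

test_that("boxplot summaries implement the adjacent-value whisker rule", {
  s <- boxplot_summary(c(1, 2, 3, 4, 5))
  expect_equal(s$median, 3)
  expect_equal(s$p25, 2)
  expect_equal(s$p75, 4)
  expect_equal(s$lower_adjacent, 1)
  expect_equal(s$upper_adjacent, 5)
  expect_length(s$outliers[[1]], 0)

  flat <- boxplot_summary(rep(7, 10))
  expect_equal(unlist(flat[, c("median", "p25", "p75", "lower_adjacent",
                               "upper_adjacent")], use.names = FALSE), rep(7, 5))

  # random vectors match a direct implementation of the whisker formula
  set.seed(111)
  for (i in 1:50) {
    v <- rnorm(sample(5:60, 1), sd = sample(1:10, 1))
    s <- boxplot_summary(v)
    q <- quantile(v, c(.25, .5, .75), names = FALSE)
    iqr <- q[3] - q[1]
    expect_equal(s$p25, q[1]); expect_equal(s$median, q[2]); expect_equal(s$p75, q[3])
    expect_equal(s$lower_adjacent, min(v[v >= q[1] - 1.5 * iqr]))
    expect_equal(s$upper_adjacent, max(v[v <= q[3] + 1.5 * iqr]))
    expect_setequal(s$outliers[[1]], v[v < q[1] - 1.5 * iqr | v > q[3] + 1.5 * iqr])
    expect_gte(s$lower_adjacent, q[1] - 1.5 * iqr)
    expect_lte(s$upper_adjacent, q[3] + 1.5 * iqr)
  }
})

test_that("empty groups are omitted with a warning record", {
  g <- factor(c("a", "a", "b"), levels = c("a", "b", "c"))
  expect_warning(s <- boxplot_summary(c(1, 2, 3), g), "Empty group")
  expect_setequal(s$group, c("a", "b"))
  expect_equal(attr(s, "warnings"), "c")
})

test_that("bivariate summaries split rates by covariate level", {
  prof <- synth_profiles(30)
  turn <- tibble::tibble(practice_id = prof$practice_id,
                         rate = ifelse(prof$ownership == "private", 40, 20))
  bs <- bivariate_summary(turn, prof)
  own <- dplyr::filter(bs, covariate == "ownership")
  expect_equal(own$median[own$group == "private"], 40)
  expect_equal(own$median[own$group == "public"], 20)
  expect_setequal(unique(bs$covariate),
                  c("size", "workload", "morbidity", "deprivation",
                    "location", "ownership", "ownership_subtype"))
})

test_that("noiseless linear outcomes are recovered exactly", {
  prof <- synth_profiles(60)
  turn <- tibble::tibble(practice_id = prof$practice_id,
                         rate = 20 + 5 * (prof$deprivation_code == 3))
  fit <- suppressWarnings(fit_turnover_regression(turn, prof, "full"))
  co <- fit$coefficients
  expect_equal(co$estimate[co$term == "constant"], 20, tolerance = 1e-10)
  expect_equal(co$estimate[co$term == "deprivation_most_deprived"], 5, tolerance = 1e-10)
  other <- co$estimate[!co$term %in% c("constant", "deprivation_most_deprived")]
  expect_true(all(abs(other) < 1e-10))
  expect_true(all(abs(fit$residuals) < 1e-10))
  expect_equal(fit$n_practices, 60)
})

test_that("robust covariance matches the explicit HC1 sandwich on a fixed 12-row dataset", {
  d <- tibble::tibble(
    practice_id = sprintf("P%d", 1:12),
    ownership = c("public", "public", "private", "private", "private", "public",
                  "private", "public", "public", "private", "private", "public"),
    ownership_subtype = "public",
    location = c("town", "city", "town", "commuting", "commuting", "town",
                 "rural", "rural", "rural", "city", "city", "commuting"),
    morbidity = 1, deprivation = 1, size_patients = 8000, workload = 1500,
    size_code = c(2L, 1L, 1L, 2L, 3L, 1L, 3L, 3L, 3L, 1L, 2L, 2L),
    morbidity_code = c(3L, 1L, 2L, 1L, 2L, 2L, 1L, 1L, 3L, 3L, 2L, 3L),
    deprivation_code = c(1L, 2L, 3L, 2L, 3L, 3L, 1L, 1L, 2L, 3L, 2L, 1L),
    workload_code = rep(c(2L, 1L), 6))
  turn <- tibble::tibble(practice_id = d$practice_id,
                         rate = c(31, 18, 44, 12, 55, 23, 38, 27, 9, 61, 35, 20))
  # nearly saturated toy design: sandwich warns about hat values close to 1,
  # which is exactly the regime worth checking against the explicit formula
  fit <- suppressWarnings(fit_turnover_regression(turn, d, "excl_workload"))
  X <- stats::model.matrix(fit$model)
  V <- oracle_hc1(X, turn$rate)
  expect_lt(max(abs(V - fit$vcov_robust)), 1e-8)
})

test_that("robust and classical SEs agree under homoskedastic noise at large n", {
  prof <- synth_profiles(2000, seed = 3)
  set.seed(4)
  turn <- tibble::tibble(practice_id = prof$practice_id,
                         rate = 30 + rnorm(2000, sd = 8))
  fit <- fit_turnover_regression(turn, prof, "full")
  classical <- sqrt(diag(stats::vcov(fit$model)))
  expect_true(all(abs(fit$coefficients$se_robust / classical - 1) < 0.10))
})

test_that("adding a constant to all outcomes shifts only the intercept", {
  prof <- synth_profiles(80, seed = 5)
  set.seed(6)
  base_rate <- 25 + 3 * (prof$workload_code == 3) + rnorm(80, sd = 5)
  f1 <- fit_turnover_regression(
    tibble::tibble(practice_id = prof$practice_id, rate = base_rate), prof, "full")
  f2 <- fit_turnover_regression(
    tibble::tibble(practice_id = prof$practice_id, rate = base_rate + 7), prof, "full")
  c1 <- f1$coefficients; c2 <- f2$coefficients
  expect_equal(c2$estimate[c2$term == "constant"],
               c1$estimate[c1$term == "constant"] + 7, tolerance = 1e-9)
  expect_equal(c2$estimate[c2$term != "constant"],
               c1$estimate[c1$term != "constant"], tolerance = 1e-9)
})

test_that("specifications omit their dummies and collinearity is reported", {
  prof <- synth_profiles(60, seed = 7)
  set.seed(8)
  turn <- tibble::tibble(practice_id = prof$practice_id, rate = rnorm(60, 30, 5))
  f_full <- fit_turnover_regression(turn, prof, "full")
  f_np <- fit_turnover_regression(turn, prof, "excl_private")
  f_nw <- fit_turnover_regression(turn, prof, "excl_workload")
  expect_true("private" %in% f_full$coefficients$term)
  expect_false("private" %in% f_np$coefficients$term)
  expect_false(any(grepl("^workload", f_nw$coefficients$term)))

  collinear <- dplyr::mutate(prof, ownership = ifelse(location == "rural",
                                                      "private", "public"),
                             workload_code = NULL,
                             workload_code = ifelse(location == "town", 3L, 1L))
  # make private a duplicate of location_rural -> rank deficient
  expect_error(fit_turnover_regression(turn, collinear, "excl_workload"),
               class = "gpturnover_estimation_error")
})

test_that("dropping workload moves the private coefficient by the omitted-variable logic", {
  # construct: private practices have high workload, workload raises turnover,
  # ownership itself has no effect. Omitting workload should push the private
  # coefficient towards the (positive) workload effect.
  set.seed(9)
  n <- 300
  prof <- synth_profiles(n, seed = 9)
  prof$ownership <- ifelse(prof$workload_code == 3,
                           ifelse(runif(n) < 0.8, "private", "public"),
                           ifelse(runif(n) < 0.2, "private", "public"))
  turn <- tibble::tibble(practice_id = prof$practice_id,
                         rate = 20 + 8 * (prof$workload_code == 3) + rnorm(n, sd = 4))
  b_full <- fit_turnover_regression(turn, prof, "full")$coefficients
  b_nw <- fit_turnover_regression(turn, prof, "excl_workload")$coefficients
  expect_gt(b_nw$estimate[b_nw$term == "private"],
            b_full$estimate[b_full$term == "private"])
})

test_that("the balanced-panel filter keeps practices observed in every year", {
  ann <- tidyr::crossing(practice_id = c("A", "B", "C"), year = 2015:2017) |>
    dplyr::mutate(rate = 30)
  expect_equal(nrow(balanced_panel_filter(ann, 2015:2017)), 9)
  gap <- ann[-2, ]  # drop A 2016
  bal <- balanced_panel_filter(gap, 2015:2017)
  expect_setequal(unique(bal$practice_id), c("B", "C"))
  expect_equal(attr(bal, "dropped_practices"), "A")
})
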