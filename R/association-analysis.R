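# Association analysis: boxplot-style summaries per covariate level and
# least-squares regressions of practice-level turnover with
# heteroskedasticity-robust (HC1) standard errors.

#' Boxplot summary with adjacent-value whiskers
#'
#' Computes, per group, the median and quartiles together with the adjacent
#' values used as whiskers: the most extreme data points inside the fences
#' `p25 - 1.5 * (p75 - p25)` and `p75 + 1.5 * (p75 - p25)`. Points outside the
#' fences are returned as outliers. Quantiles use the default rank-interpolation
#' convention (`stats::quantile`, type 7), fixed project-wide.
#'
#' @param values Numeric vector of rates (or any measure).
#' @param groups Optional vector of group labels, recycled against `values`;
#'   by default all values form one group.
#' @return A tibble with one row per non-empty group: `group`, `n`, `median`,
#'   `p25`, `p75`, `lower_adjacent`, `upper_adjacent` and a list column
#'   `outliers`. Empty groups are omitted and recorded in the `warnings`
#'   attribute (with a warning).
#' @export
boxplot_summary <- function(values, groups = NULL) {
  if (!is.numeric(values)) abort_param("`values` must be numeric.")
  groups <- groups %||% rep("all", length(values))
  if (length(groups) != length(values)) abort_param("`groups` must match `values` in length.")

  lev <- if (is.factor(groups)) levels(groups) else sort(unique(as.character(groups)))
  groups <- as.character(groups)
  empty <- character()
  rows <- lapply(lev, function(g) {
    v <- values[groups == g & !is.na(values)]
    if (length(v) == 0) {
      empty <<- c(empty, g)
      return(NULL)
    }
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    iqr <- q[3] - q[1]
    lo_fence <- q[1] - 1.5 * iqr
    hi_fence <- q[3] + 1.5 * iqr
    tibble(group = g, n = length(v),
           median = q[2], p25 = q[1], p75 = q[3],
           lower_adjacent = min(v[v >= lo_fence]),
           upper_adjacent = max(v[v <= hi_fence]),
           outliers = list(v[v < lo_fence | v > hi_fence]))
  })
  if (length(empty) > 0) {
    warn(sprintf("Empty group(s) omitted from summary: %s", paste(empty, collapse = ", ")))
  }
  structure(bind_rows(rows), warnings = empty)
}

# covariate -> profile column used by the bivariate and regression analyses
covariate_columns <- function() {
  c(size = "size_code", workload = "workload_code", morbidity = "morbidity_code",
    deprivation = "deprivation_code", location = "location",
    ownership = "ownership", ownership_subtype = "ownership_subtype")
}

#' Bivariate turnover summaries per covariate level
#'
#' One adjacent-value boxplot summary per level of each practice covariate
#' (tercile codes for size, workload, morbidity and deprivation; categories
#' for location, ownership and ownership subtype).
#'
#' @param turnover Output of [practice_average()] (columns `practice_id`,
#'   `rate`).
#' @param profiles Output of [build_profiles()].
#' @return A tibble of boxplot summaries with leading columns `covariate` and
#'   `group`. Practices lacking a profile are excluded and listed in the
#'   `excluded` attribute.
#' @export
bivariate_summary <- function(turnover, profiles) {
  check_columns(turnover, c("practice_id", "rate"), "`turnover`")
  d <- inner_join(turnover, profiles, by = "practice_id")
  excluded <- setdiff(turnover$practice_id, d$practice_id)
  if (length(excluded) > 0) {
    warn(sprintf("%d practice(s) without a profile excluded from the bivariate summary.",
                 length(excluded)))
  }

  cols <- covariate_columns()
  out <- lapply(names(cols), function(cv) {
    g <- d[[cols[[cv]]]]
    keep <- !is.na(g)
    s <- boxplot_summary(d$rate[keep], as.character(g[keep]))
    mutate(s, covariate = cv)
  })
  bind_rows(out) |>
    relocate(all_of(c("covariate", "group"))) |>
    structure(excluded = excluded)
}

# Build the 0/1 regressor frame for one specification. Reference categories:
# lowest terciles, public ownership, city location. Missing-category dummies
# (code 0) are auxiliary: included when present, flagged in the output.
build_design <- function(d, specification) {
  ter <- function(code, prefix, top_label) {
    out <- tibble(!!paste0(prefix, "_medium") := as.integer(code == 2L),
                  !!paste0(prefix, "_", top_label) := as.integer(code == 3L))
    if (any(code == 0L, na.rm = TRUE)) {
      out[[paste0(prefix, "_missing")]] <- as.integer(code == 0L)
    }
    out
  }
  X <- bind_cols(
    ter(d$size_code, "size", "largest"),
    if (specification != "excl_workload") ter(d$workload_code, "workload", "highest"),
    ter(d$morbidity_code, "morbidity", "highest"),
    ter(d$deprivation_code, "deprivation", "most_deprived"),
    tibble(location_commuting = as.integer(d$location == "commuting"),
           location_town = as.integer(d$location == "town"),
           location_rural = as.integer(d$location == "rural")),
    if (specification != "excl_private") tibble(private = as.integer(d$ownership == "private"))
  )
  X
}

#' Regression of practice-level turnover on practice characteristics
#'
#' Fits, by ordinary least squares, the practice-level model
#' \deqn{Turnover_j = \alpha + \beta_1 Size_j + \beta_2 Morbidity_j +
#'   \beta_3 Deprivation_j + \beta_4 Private_j + \beta_5 Location_j +
#'   \beta_6 Workload_j + \varepsilon_j}
#' where size, workload, morbidity and deprivation enter as tercile dummies
#' (reference: lowest tercile), location as category dummies (reference: city)
#' and ownership as a private indicator (reference: public). Standard errors
#' are heteroskedasticity-robust with HC1 small-sample scaling
#' (`sandwich::vcovHC(type = "HC1")`), the convention of common econometric
#' software; p-values use the t distribution with `n - k` degrees of freedom.
#'
#' Missing-category dummies (tercile code 0) are included when present but
#' flagged as auxiliary in the coefficient table.
#'
#' @param turnover Output of [practice_average()].
#' @param profiles Output of [build_profiles()].
#' @param specification `"full"`, `"excl_private"` (private dummy omitted) or
#'   `"excl_workload"` (workload dummies omitted).
#' @return An object of class `turnover_fit`: a list with `coefficients` (a
#'   tibble of estimates, robust SEs, t statistics, p-values and significance
#'   stars at the 0.05 / 0.01 / 0.001 thresholds), `n_practices`, `vcov_robust`,
#'   `residuals`, `specification` and the underlying `lm` fit.
#' @export
fit_turnover_regression <- function(turnover, profiles,
                                    specification = c("full", "excl_private", "excl_workload")) {
  specification <- match.arg(specification)
  check_columns(turnover, c("practice_id", "rate"), "`turnover`")
  d <- inner_join(select(turnover, all_of(c("practice_id", "rate"))),
                  profiles, by = "practice_id")
  if (anyNA(d$workload_code) && specification != "excl_workload") {
    abort_input(sprintf(
      "%d practice(s) have no computable workload; use specification = \"excl_workload\" or drop them.",
      sum(is.na(d$workload_code))))
  }

  X <- build_design(d, specification)
  dd <- bind_cols(tibble(rate = d$rate), X)
  if (nrow(dd) <= ncol(X) + 1) {
    abort_param("More design columns than practices; the model cannot be estimated.")
  }

  fit <- stats::lm(rate ~ ., data = dd)
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    abort(sprintf("Design matrix is rank deficient; collinear column(s): %s",
                  paste(bad, collapse = ", ")),
          class = "gpturnover_estimation_error", columns = bad)
  }

  V <- sandwich::vcovHC(fit, type = "HC1")
  est <- stats::coef(fit)
  se <- sqrt(diag(V))
  stat <- est / se
  df <- stats::df.residual(fit)
  p <- 2 * stats::pt(abs(stat), df = df, lower.tail = FALSE)
  stars <- cut(p, c(-Inf, 0.001, 0.01, 0.05, Inf),
               labels = c("***", "**", "*", ""))
  term <- sub("^\\(Intercept\\)$", "constant", names(est))

  coefs <- tibble(term = term, estimate = unname(est), se_robust = unname(se),
                  statistic = unname(stat), p_value = unname(p),
                  stars = as.character(stars),
                  auxiliary = grepl("_missing$", term))

  structure(list(coefficients = coefs, n_practices = nrow(dd),
                 specification = specification, vcov_robust = V,
                 residuals = stats::residuals(fit), model = fit),
            class = "turnover_fit")
}

#' @export
print.turnover_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Practice-level turnover regression (%s), N = %d\n",
              x$specification, x$n_practices))
  cat("Robust (HC1) standard errors in parentheses; * p<0.05 ** p<0.01 *** p<0.001\n\n")
  co <- x$coefficients
  lines <- sprintf("  %-26s %9.*f%-3s (%.*f)%s", co$term, digits, co$estimate,
                   co$stars, digits, co$se_robust,
                   ifelse(co$auxiliary, "  [auxiliary]", ""))
  cat(lines, sep = "\n")
  invisible(x)
}

#' Restrict an annual panel to practices observed in every year
#'
#' The balanced-panel sensitivity analysis keeps only practices with a
#' non-missing annual observation in each year of the span.
#'
#' @param annual Output of [annual_turnover()] (imputed rates count as
#'   observations).
#' @param years Vector of calendar years defining the span.
#' @return The filtered panel, with the dropped practice ids in the
#'   `dropped_practices` attribute.
#' @export
balanced_panel_filter <- function(annual, years) {
  check_columns(annual, c("practice_id", "year", "rate"), "`annual`")
  years <- sort(unique(as.integer(years)))
  complete <- annual |>
    filter(!is.na(.data$rate), .data$year %in% years) |>
    distinct(.data$practice_id, .data$year) |>
    count(.data$practice_id) |>
    filter(.data$n == length(years)) |>
    pull("practice_id")
  dropped <- setdiff(unique(annual$practice_id), complete)
  annual |>
    filter(.data$practice_id %in% complete, .data$year %in% years) |>
    structure(dropped_practices = dropped)
}
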