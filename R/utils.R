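# Internal helpers shared across modules.

#' @importFrom rlang abort warn .data %||%
#' @importFrom dplyr filter mutate summarise group_by ungroup arrange select
#'   left_join inner_join semi_join anti_join count n n_distinct distinct
#'   bind_rows bind_cols case_when across all_of lag first last rename
#'   relocate if_else pull
#' @importFrom tibble tibble as_tibble
#' @importFrom lubridate year month floor_date rollforward days_in_month %m+%
NULL

# first / last day of the calendar month containing `d`
month_first <- function(d) lubridate::floor_date(d, "month")
month_last <- function(d) lubridate::rollforward(d)

# shift a date by `k` calendar months (safe for first-of-month dates)
add_months <- function(d, k) d %m+% months(k)

# sample() without the length-1 surprise
resample <- function(x, size = 1, replace = FALSE, prob = NULL) {
  x[sample.int(length(x), size, replace = replace, prob = prob)]
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x)

is_count <- function(x) is_scalar_number(x) && x >= 1 && x == as.integer(x)

abort_config <- function(field, msg) {
  abort(sprintf("Invalid configuration: `%s` %s", field, msg),
        class = "gpturnover_config_error", field = field)
}

abort_input <- function(msg, ..., class = "gpturnover_input_error") {
  abort(msg, class = class, ...)
}

abort_param <- function(msg, ...) {
  abort(msg, class = "gpturnover_parameter_error", ...)
}

# check that a data frame has the required columns
check_columns <- function(x, cols, what) {
  missing <- setdiff(cols, names(x))
  if (length(missing) > 0) {
    abort_input(sprintf("%s is missing required column(s): %s",
                        what, paste(missing, collapse = ", ")))
  }
  invisible(x)
}

# Date column validation; reports offending row indices as the spec of the
# input contract requires.
check_dates <- function(x, col, what) {
  v <- x[[col]]
  if (!inherits(v, "Date")) {
    abort_input(sprintf("%s column `%s` must be of class Date", what, col))
  }
  bad <- which(is.na(v))
  if (length(bad) > 0) {
    abort_input(sprintf(
      "%s has missing/malformed `%s` at row(s): %s", what, col,
      paste(utils::head(bad, 10), collapse = ", ")))
  }
  invisible(x)
}

# wrap a pipeline stage so failures carry the stage name
with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("Pipeline stage `%s` failed: %s", stage, conditionMessage(e)),
          class = "gpturnover_stage_error", parent = e)
  })
}
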