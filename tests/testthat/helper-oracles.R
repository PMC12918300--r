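# Independent brute-force oracles, deliberately written as plain loops over
# rows so they share no code path with the package implementations.

oracle_workforce <- function(events, min_days) {
  key <- paste(events$practice_id, format(events$date, "%Y-%m"), events$physician_id)
  out <- list()
  for (k in unique(key)) {
    rows <- events[key == k, ]
    nd <- length(unique(rows$date))
    if (nd >= min_days) {
      out[[length(out) + 1]] <- data.frame(
        practice_id = rows$practice_id[1],
        month = as.Date(paste0(format(rows$date[1], "%Y-%m"), "-01")),
        physician_id = rows$physician_id[1],
        n_days = nd)
    }
  }
  df <- do.call(rbind, out)
  if (is.null(df)) {
    return(data.frame(practice_id = character(), month = as.Date(character()),
                      physician_id = character(), n_days = integer()))
  }
  df[order(df$practice_id, df$month, df$physician_id), , drop = FALSE]
}

oracle_spells <- function(events, gap_days, data_end) {
  pair <- paste(events$physician_id, events$practice_id)
  out <- list()
  for (p in unique(pair)) {
    rows <- events[pair == p, ]
    dates <- sort(unique(rows$date))
    seg_start <- dates[1]
    prev <- dates[1]
    flush <- function(first, last) {
      data.frame(physician_id = rows$physician_id[1],
                 practice_id = rows$practice_id[1],
                 first_date = first, last_date = last,
                 duration_days = as.integer(last - first),
                 censored = as.numeric(data_end - last) < gap_days)
    }
    for (d in as.list(dates[-1])) {
      if (as.numeric(d - prev) >= gap_days) {
        out[[length(out) + 1]] <- flush(seg_start, prev)
        seg_start <- d
      }
      prev <- d
    }
    out[[length(out) + 1]] <- flush(seg_start, prev)
  }
  df <- do.call(rbind, out)
  df[order(df$practice_id, df$physician_id, df$first_date), , drop = FALSE]
}

# last day of the month `k` months after the (first-of-month) date `d`,
# via base seq.Date only
oracle_month_shift_end <- function(d, k) {
  seq(d, by = "month", length.out = k + 2)[k + 2] - 1
}

# direct enumeration of the monthly within-horizon rate over members
oracle_monthly_turnover <- function(workforce, spells, h, data_end,
                                    policy = "as_ongoing") {
  rows <- list()
  for (i in seq_len(nrow(workforce))) {
    w <- workforce[i, ]
    m_end <- oracle_month_shift_end(w$month, 0)
    cand <- spells[spells$physician_id == w$physician_id &
                     spells$practice_id == w$practice_id &
                     spells$first_date <= m_end &
                     spells$last_date >= w$month, ]
    stopifnot(nrow(cand) == 1)
    horizon_end <- oracle_month_shift_end(w$month, h)
    if (horizon_end > data_end) next
    ended <- cand$last_date <= horizon_end
    amb <- cand$censored && ended
    if (policy == "as_ongoing" && amb) ended <- FALSE
    if (policy == "exclude" && amb) next
    rows[[length(rows) + 1]] <- data.frame(
      practice_id = w$practice_id, month = w$month, ended = ended)
  }
  df <- do.call(rbind, rows)
  if (is.null(df)) {
    return(data.frame(practice_id = character(), month = as.Date(character()),
                      rate = numeric()))
  }
  out <- aggregate(ended ~ practice_id + month, df, function(v) 100 * mean(v))
  names(out)[names(out) == "ended"] <- "rate"
  out[order(out$practice_id, out$month), ]
}

# explicit HC1 sandwich covariance from the design matrix and residuals
oracle_hc1 <- function(X, y) {
  n <- nrow(X); k <- ncol(X)
  bread <- solve(t(X) %*% X)
  beta <- bread %*% t(X) %*% y
  u <- as.vector(y - X %*% beta)
  meat <- t(X) %*% (X * u^2)
  (n / (n - k)) * bread %*% meat %*% bread
}

# random event sets for oracle-equivalence checks
random_events <- function(n_events, n_phys = 3, n_prac = 2,
                          start = as.Date("2013-01-01"), span_days = 1200) {
  tibble::tibble(
    physician_id = sample(sprintf("gp%02d", seq_len(n_phys)), n_events, replace = TRUE),
    practice_id = sample(sprintf("p%02d", seq_len(n_prac)), n_events, replace = TRUE),
    date = start + sample.int(span_days, n_events, replace = TRUE) - 1
  )
}

# small helper: events giving physician `id` exactly `n_days` distinct days
# in one month at one practice
days_in_month_events <- function(id, practice, year_month, days) {
  tibble::tibble(
    physician_id = id, practice_id = practice,
    date = as.Date(paste0(year_month, "-01")) + days - 1
  )
}
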