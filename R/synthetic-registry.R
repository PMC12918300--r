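# Synthetic care-registry generator.
#
# The generator emulates the data-generating process the analysis assumes: each
# practice holds a number of permanent and temporary staffing slots; each slot
# is occupied by a succession of physicians whose spells end according to a
# per-contract-type monthly exit process (memoryless for permanent, freelance
# and registrar contracts; deterministic contract expiry for fixed-term and
# foundation placements), with immediate replacement. Physicians consult on a
# random subset of distinct days each month.
#
# Exit convention: when a hazard-driven spell ends, the physician's final month
# is a short wind-down (1-5 consultation days early in the month), below every
# workforce day threshold. A workforce member of month m therefore faces
# exactly twelve monthly exit opportunities inside the 12-month horizon, so the
# within-horizon exit probability is exactly 1 - (1 - q)^12 -- the closed form
# used by the recovery tests. Employment end dates are administrative: the last
# day of the final (wind-down) month.

# theoretical tercile of a score under N(1, sd); used for the hazard ground
# truth so that per-practice RNG substreams stay independent of each other
theoretical_tercile <- function(value, sd) {
  if (sd <= 0) return(rep(1L, length(value)))
  cuts <- stats::qnorm(c(1 / 3, 2 / 3), mean = 1, sd = sd)
  1L + (value > cuts[1]) + (value > cuts[2])
}

#' Covariate ground truth for a generated registry
#'
#' Recomputes, deterministically from the practice attribute table, the
#' quantities the generator used as ground truth: theoretical-tercile codes of
#' the case-mix and deprivation scores and the resulting additive shift of the
#' permanent monthly exit hazard. Used by effect-recovery tests.
#'
#' @param config The `registry_config` the registry was generated with.
#' @param attributes The `attributes` table of [generate_registry()] output.
#' @return A tibble `practice_id`, `morbidity`, `deprivation`,
#'   `morbidity_tercile`, `deprivation_tercile`, `private`, `hazard_shift`,
#'   `exit_hazard_permanent`.
#' @export
generate_covariate_panel <- function(config, attributes) {
  if (!inherits(config, "registry_config")) {
    abort_param("`config` must be created by registry_config().")
  }
  check_columns(attributes, c("practice_id", "ownership", "morbidity", "deprivation"),
                "`attributes`")
  eff <- config$covariate_effects
  tibble(
    practice_id = attributes$practice_id,
    morbidity = attributes$morbidity,
    deprivation = attributes$deprivation,
    morbidity_tercile = theoretical_tercile(attributes$morbidity, config$morbidity_sd),
    deprivation_tercile = theoretical_tercile(attributes$deprivation, config$deprivation_sd),
    private = as.integer(attributes$ownership == "private")
  ) |>
    mutate(hazard_shift = eff[["morbidity"]] * (.data$morbidity_tercile - 1L) +
             eff[["deprivation"]] * (.data$deprivation_tercile - 1L) +
             eff[["private"]] * .data$private,
           exit_hazard_permanent = pmin(0.99, pmax(
             0, config$exit_hazard_by_contract[["permanent"]] + .data$hazard_shift)))
}

# simulate one practice inside its own RNG substream; returns the four tables
simulate_practice <- function(idx, cfg, seed) {
  set.seed(seed)
  y0 <- cfg$years[1]; y1 <- cfg$years[2]
  n_years <- y1 - y0 + 1L
  T_m <- n_years * 12L
  month_starts <- seq(as.Date(sprintf("%d-01-01", y0)), by = "month", length.out = T_m)
  month_lens <- as.integer(lubridate::days_in_month(month_starts))
  pid <- sprintf("pcc%04d", idx)

  # ---- attributes --------------------------------------------------------
  subtype <- resample(names(cfg$ownership_subtype_probs), 1,
                      prob = cfg$ownership_subtype_probs)
  ownership <- if (subtype == "public") "public" else "private"
  location <- resample(names(cfg$location_probs), 1, prob = cfg$location_probs)
  morbidity <- stats::rnorm(1, 1, cfg$morbidity_sd)
  deprivation <- stats::rnorm(1, 1, cfg$deprivation_sd)
  pat_base <- max(1000, stats::rnorm(1, cfg$patients_per_practice[["mean"]],
                                     cfg$patients_per_practice[["sd"]]))

  open_year <- y0; first_m <- 1L
  if (stats::runif(1) < cfg$p_open_close[["open"]] && n_years > 1) {
    open_year <- resample((y0 + 1):y1, 1)
    first_m <- (open_year - y0) * 12L + resample(1:12, 1)
  }
  close_year <- NA_integer_; last_m <- T_m
  if (stats::runif(1) < cfg$p_open_close[["close"]] && open_year < y1) {
    close_year <- resample((open_year + 1):y1, 1)
    last_m <- (close_year - y0) * 12L + resample(1:12, 1)
  }

  # ---- ground-truth exit hazard -----------------------------------------
  eff <- cfg$covariate_effects
  shift <- eff[["morbidity"]] * (theoretical_tercile(morbidity, cfg$morbidity_sd) - 1L) +
    eff[["deprivation"]] * (theoretical_tercile(deprivation, cfg$deprivation_sd) - 1L) +
    eff[["private"]] * (ownership == "private")
  q_perm <- min(0.99, max(0, cfg$exit_hazard_by_contract[["permanent"]] + shift))
  hz <- cfg$exit_hazard_by_contract

  # ---- staffing slots ----------------------------------------------------
  # `temporary_share` targets the share of the *regular workforce* on
  # temporary contracts. Hazard-driven spells spend one month per spell in a
  # sub-threshold wind-down, so a slot's roster availability is E[D]/(E[D]+1)
  # = 1/(1+q); the slot share is inflated accordingly.
  n_perm <- 1L + stats::rpois(1, max(0, cfg$mean_permanent_staff - 1))
  s <- cfg$temporary_share
  avail <- function(q) 1 / (1 + q)
  a_p <- avail(q_perm)
  a_by_type <- c(fixed_term = 1, freelance = avail(hz[["freelance"]]),
                 registrar = avail(hz[["registrar"]]), foundation = 1)
  a_t <- sum(cfg$temp_contract_probs * a_by_type[names(cfg$temp_contract_probs)])
  s_slot <- if (s > 0) s * a_p / (a_t + s * (a_p - a_t)) else 0
  nt_exp <- n_perm * s_slot / (1 - s_slot)
  n_temp <- floor(nt_exp) + (stats::runif(1) < (nt_exp - floor(nt_exp)))

  # ---- spells ------------------------------------------------------------
  # `temp_contract_probs` states the target composition of the temporary
  # *workforce months*; since occupants hold their slot for their expected
  # spell length, draws of new occupants are inverse-duration weighted.
  exp_months <- c(
    fixed_term = cfg$fixed_contract_mean_months,
    freelance = 1 / hz[["freelance"]] + 1,
    registrar = 1 / hz[["registrar"]] + 1,
    foundation = 6)
  occ_probs <- cfg$temp_contract_probs / exp_months[names(cfg$temp_contract_probs)]
  occ_probs <- occ_probs / sum(occ_probs)

  sp <- list(); k <- 0L; phys_counter <- 0L
  for (slot in seq_len(n_perm + n_temp)) {
    is_temp <- slot > n_perm
    t <- first_m
    while (t <= last_m) {
      phys_counter <- phys_counter + 1L
      contract <- if (!is_temp) "permanent" else
        resample(names(occ_probs), 1, prob = occ_probs)
      intensity <- resample(cfg$consult_days_per_month$intensity, 1,
                            prob = cfg$consult_days_per_month$intensity_probs)
      winddown <- contract %in% c("permanent", "freelance", "registrar")
      if (winddown) {
        q <- if (contract == "permanent") q_perm else hz[[contract]]
        D <- if (q <= 0) Inf else stats::rgeom(1, q) + 1
      } else if (contract == "fixed_term") {
        D <- stats::rgeom(1, 1 / cfg$fixed_contract_mean_months) + 1
      } else { # foundation: fixed 6-month placement
        D <- 6
      }
      full_end <- t + D - 1
      truncated <- if (winddown) full_end >= last_m else full_end > last_m
      k <- k + 1L
      if (truncated) {
        sp[[k]] <- list(phys = phys_counter, contract = contract,
                        intensity = intensity, start_m = t,
                        full_end = last_m, wd_m = NA_integer_,
                        trunc = if (!is.na(close_year)) "closure" else "data_end")
        t <- last_m + 1L
      } else {
        wd_m <- if (winddown) as.integer(full_end + 1L) else NA_integer_
        sp[[k]] <- list(phys = phys_counter, contract = contract,
                        intensity = intensity, start_m = t,
                        full_end = as.integer(full_end), wd_m = wd_m,
                        trunc = "none")
        t <- as.integer(if (winddown) wd_m else full_end) + 1L
      }
    }
  }
  spells <- tibble(
    phys = vapply(sp, `[[`, integer(1), "phys"),
    contract = vapply(sp, `[[`, character(1), "contract"),
    intensity = vapply(sp, `[[`, numeric(1), "intensity"),
    start_m = vapply(sp, function(x) as.integer(x$start_m), integer(1)),
    full_end = vapply(sp, `[[`, integer(1), "full_end"),
    wd_m = vapply(sp, `[[`, integer(1), "wd_m"),
    trunc = vapply(sp, `[[`, character(1), "trunc")
  )
  spells$physician_id <- sprintf("gp-%s-%04d", pid, spells$phys)

  # one leave per eligible long permanent spell: a mid-spell block of
  # consultation-free months, short enough for the gap rule to absorb
  n_full <- spells$full_end - spells$start_m + 1L
  max_leave_m <- min(9L, cfg$leave_max_days %/% 31L)
  spells$leave_start <- NA_integer_; spells$leave_len <- 0L
  if (cfg$leave_prob > 0 && max_leave_m >= 1) {
    elig <- which(spells$contract == "permanent" & n_full >= 24L)
    for (i in elig) {
      if (stats::runif(1) < cfg$leave_prob) {
        len <- resample(1:max_leave_m, 1)
        off <- resample(2:(n_full[i] - len), 1) # strictly inside the spell
        spells$leave_start[i] <- spells$start_m[i] + off - 1L
        spells$leave_len[i] <- len
      }
    }
  }

  # ---- physician-months --------------------------------------------------
  reps <- n_full
  pm_m <- unlist(Map(seq.int, spells$start_m, spells$full_end), use.names = FALSE)
  pm_spell <- rep(seq_len(nrow(spells)), reps)
  pm_kind <- rep("full", length(pm_m))
  # leave months produce no consultations
  ls <- spells$leave_start[pm_spell]; ll <- spells$leave_len[pm_spell]
  on_leave <- !is.na(ls) & pm_m >= ls & pm_m < ls + ll
  pm_m <- pm_m[!on_leave]; pm_spell <- pm_spell[!on_leave]; pm_kind <- pm_kind[!on_leave]
  # wind-down months
  wd_idx <- which(!is.na(spells$wd_m))
  pm_m <- c(pm_m, spells$wd_m[wd_idx])
  pm_spell <- c(pm_spell, wd_idx)
  pm_kind <- c(pm_kind, rep("winddown", length(wd_idx)))
  # ramp-up window of a mid-panel opening: sub-threshold activity
  if (first_m > 1L && cfg$ramp_up_months > 0) {
    ramp_months <- first_m:min(first_m + cfg$ramp_up_months - 1L, last_m)
    pm_kind[pm_kind == "full" & pm_m %in% ramp_months] <- "ramp"
  }

  wk <- cfg$consult_days_per_month$workdays
  n_days <- integer(length(pm_m))
  is_full <- pm_kind == "full"
  n_days[is_full] <- stats::rbinom(sum(is_full), wk, spells$intensity[pm_spell[is_full]])
  n_days[pm_kind == "ramp"] <- resample(3:8, sum(pm_kind == "ramp"), replace = TRUE)
  n_days[pm_kind == "winddown"] <- resample(1:5, sum(pm_kind == "winddown"), replace = TRUE)

  keep <- n_days > 0L
  pm_m <- pm_m[keep]; pm_spell <- pm_spell[keep]; pm_kind <- pm_kind[keep]
  n_days <- n_days[keep]

  # draw the distinct consultation days: expand candidate days per
  # physician-month, rank uniform noise within each month, keep the first
  # n_days -- a uniform sample without replacement
  L <- ifelse(pm_kind == "winddown", 10L, month_lens[pm_m])
  row_id <- rep(seq_along(pm_m), L)
  day <- sequence(L)
  u <- stats::runif(length(day))
  ord <- order(row_id, u)
  pos <- sequence(L)
  sel <- ord[pos <= n_days[row_id[ord]]]
  ev_row <- row_id[sel]
  ev_date <- month_starts[pm_m[ev_row]] + (day[sel] - 1L)

  events <- tibble(
    physician_id = spells$physician_id[pm_spell[ev_row]],
    practice_id = pid,
    date = ev_date,
    n_visits = 4L + stats::rbinom(length(ev_row), 6, 0.5)
  ) |>
    arrange(.data$physician_id, .data$date)

  # ---- employment records (administrative month-resolution dates) --------
  end_m <- ifelse(!is.na(spells$wd_m), spells$wd_m, spells$full_end)
  end_date <- month_last(month_starts[end_m])
  end_date[spells$trunc == "data_end"] <- NA # still employed at data end
  employment <- tibble(
    physician_id = spells$physician_id,
    practice_id = pid,
    contract = spells$contract,
    start_date = month_starts[spells$start_m],
    end_date = end_date
  )

  # ---- registration counts ----------------------------------------------
  months_open <- first_m:last_m
  registration <- tibble(
    practice_id = pid,
    month = month_starts[months_open],
    patients = as.integer(round(pat_base * exp(stats::rnorm(length(months_open), 0, 0.02))))
  )

  attributes <- tibble(
    practice_id = pid, ownership = ownership, ownership_subtype = subtype,
    location = location, morbidity = morbidity, deprivation = deprivation,
    open_year = as.integer(open_year), close_year = as.integer(close_year)
  )

  list(events = events, employment = employment,
       registration = registration, attributes = attributes)
}

#' Generate a synthetic care registry
#'
#' Simulates consultation events, employment records, monthly registration
#' counts and practice attributes with the statistical structure the turnover
#' analysis assumes (see [registry_config()] for the process and its
#' parameters). Output is fully reproducible: one root seed spawns one RNG
#' substream per practice, so `n_practices` can grow without perturbing
#' existing practices.
#'
#' @param config A `registry_config`.
#' @return A list of class `synthetic_registry` with tibbles `events`
#'   (`physician_id`, `practice_id`, `date`, `n_visits`), `employment`,
#'   `registration`, `attributes`, plus the `config`.
#' @export
generate_registry <- function(config) {
  if (!inherits(config, "registry_config")) {
    abort_param("`config` must be created by registry_config() or read_registry_config().")
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))

  set.seed(config$seed)
  practice_seeds <- sample.int(.Machine$integer.max - 1L, config$n_practices)

  parts <- lapply(seq_len(config$n_practices), function(i) {
    simulate_practice(i, config, practice_seeds[i])
  })

  structure(list(
    events = bind_rows(lapply(parts, `[[`, "events")),
    employment = bind_rows(lapply(parts, `[[`, "employment")),
    registration = bind_rows(lapply(parts, `[[`, "registration")),
    attributes = bind_rows(lapply(parts, `[[`, "attributes")),
    config = config
  ), class = "synthetic_registry")
}

#' @export
print.synthetic_registry <- function(x, ...) {
  cat(sprintf(paste0(
    "Synthetic care registry: %d practices, %d-%d\n",
    "  %s consultation events, %d physicians, %d employment records\n"),
    x$config$n_practices, x$config$years[1], x$config$years[2],
    format(nrow(x$events), big.mark = ","),
    dplyr::n_distinct(x$employment$physician_id), nrow(x$employment)))
  invisible(x)
}
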