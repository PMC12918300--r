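# Configuration object for the synthetic care-registry generator.

contract_types <- function() {
  c("permanent", "fixed_term", "freelance", "registrar", "foundation")
}

check_distribution <- function(p, field, names_expected = NULL) {
  if (!is.numeric(p) || anyNA(p)) abort_config(field, "must be a numeric probability vector.")
  if (any(p < 0 | p > 1)) abort_config(field, "has entries outside [0, 1].")
  if (abs(sum(p) - 1) > 1e-8) abort_config(field, "must sum to 1.")
  if (!is.null(names_expected) && !setequal(names(p), names_expected)) {
    abort_config(field, sprintf("must be named over {%s}.",
                                paste(names_expected, collapse = ", ")))
  }
  invisible(p)
}

#' Configuration of the synthetic care registry
#'
#' Bundles and validates every parameter of the synthetic registry generator.
#' The defaults emulate the regional panel the analysis is designed for: about
#' 160 practices observed 2010-2019, 55% publicly owned (private practices
#' split between investor-owned chains, a national GP partnership, local
#' chains and GP-owned practices), a regular workforce of roughly six
#' physicians per practice at the 10-day threshold, about one fifth of the
#' workforce on temporary contracts, a permanent-staff monthly exit hazard of
#' 0.0134 (about 15% per year), daily consultation volumes with interquartile
#' range 6-8 visits, case-mix and deprivation scores centred on 1, and a small
#' yearly probability of practice openings and closures producing an
#' unbalanced panel.
#'
#' @param n_practices Number of practices.
#' @param years Length-2 integer vector, inclusive calendar-year span.
#' @param seed Integer RNG seed. One root seed spawns one substream per
#'   practice, so extending `n_practices` does not perturb existing practices.
#' @param share_private Proportion of privately owned practices.
#' @param ownership_subtype_probs Distribution over
#'   `public, investor_chain, gp_partnership, local_chain, gp_owned`; the four
#'   private entries must sum to `share_private`.
#' @param location_probs Distribution over `city, commuting, town, rural`.
#' @param mean_permanent_staff Expected permanent physicians per practice
#'   (at least 1; the count is `1 + Poisson(mean - 1)`).
#' @param temporary_share Target share of the regular workforce on temporary
#'   contracts, in `[0, 1)` (the generator inflates the slot share to offset
#'   the sub-threshold wind-down months of hazard-driven spells).
#' @param temp_contract_probs Target composition of the temporary workforce
#'   (month shares) over `fixed_term, freelance, registrar, foundation`;
#'   occupant draws are inverse-duration weighted to achieve it.
#' @param exit_hazard_by_contract Named monthly probabilities that an ongoing
#'   spell ends, for `permanent`, `freelance` and `registrar` (memoryless
#'   processes). Must be strictly positive for the temporary types. Fixed-term
#'   and foundation contracts end deterministically at contract expiry instead
#'   (see `fixed_contract_mean_months`; foundation placements last 6 months),
#'   but their entries are validated all the same.
#' @param fixed_contract_mean_months Mean fixed-term contract length, months.
#' @param consult_days_per_month List describing the distinct-consultation-day
#'   distribution: `workdays` (monthly consulting opportunities), `intensity`
#'   (per-day consulting probabilities defining physician types) and
#'   `intensity_probs` (mixture weights). The default mixture straddles the
#'   10/15/20-day workforce thresholds.
#' @param visits_per_day_iqr Target interquartile range of visits per
#'   consultation day (realism check only; head counts drive the analysis).
#' @param patients_per_practice Named vector `mean`, `sd` of the practice-level
#'   registered-patient count.
#' @param morbidity_sd,deprivation_sd Spread of the practice-level case-mix /
#'   deprivation scores around 1.
#' @param p_open_close Named per-practice probabilities `open` (practice opens
#'   after the panel start) and `close` (practice closes before the panel end).
#' @param ramp_up_months Months of sub-threshold activity after a mid-panel
#'   opening (a newly opened practice has no regular workforce while it builds
#'   its patient list).
#' @param leave_prob Probability that a long permanent spell contains one
#'   consultation-free leave.
#' @param leave_max_days Maximum leave length in days; must stay below 365 so
#'   the gap rule absorbs leaves without splitting spells.
#' @param covariate_effects Named additive shifts of the *permanent* monthly
#'   exit hazard: `morbidity` and `deprivation` per tercile step (terciles of
#'   the theoretical score distribution), `private` for private ownership.
#'   Ground truth for effect-recovery tests.
#'
#' @return A validated list of class `registry_config`.
#' @export
registry_config <- function(
    n_practices = 160,
    years = c(2010, 2019),
    seed = 1L,
    share_private = 0.45,
    ownership_subtype_probs = c(public = 0.55, investor_chain = 0.25,
                                gp_partnership = 0.06, local_chain = 0.04,
                                gp_owned = 0.10),
    location_probs = c(city = 49, commuting = 11, town = 17, rural = 22) / 99,
    mean_permanent_staff = 5.3,
    temporary_share = 0.20,
    temp_contract_probs = c(fixed_term = 0.4, freelance = 0.4,
                            registrar = 0.1, foundation = 0.1),
    exit_hazard_by_contract = c(permanent = 0.0134, fixed_term = 0.25,
                                freelance = 0.25, registrar = 1 / 60,
                                foundation = 1 / 6),
    fixed_contract_mean_months = 4,
    consult_days_per_month = list(workdays = 22L,
                                  intensity = c(0.92, 0.78, 0.50),
                                  intensity_probs = c(0.20, 0.45, 0.35)),
    visits_per_day_iqr = c(6, 8),
    patients_per_practice = c(mean = 8665, sd = 3802),
    morbidity_sd = 0.11,
    deprivation_sd = 0.36,
    p_open_close = c(open = 0.09, close = 0.07),
    ramp_up_months = 3,
    leave_prob = 0.05,
    leave_max_days = 270,
    covariate_effects = c(morbidity = 0, deprivation = 0, private = 0)) {

  if (!is_count(n_practices)) abort_config("n_practices", "must be a positive integer.")
  if (length(years) != 2 || any(years != as.integer(years)) || years[1] > years[2]) {
    abort_config("years", "must be two ordered calendar years.")
  }
  if (!is_scalar_number(seed) || seed != as.integer(seed)) {
    abort_config("seed", "must be a single integer.")
  }
  if (!is_scalar_number(share_private) || share_private < 0 || share_private > 1) {
    abort_config("share_private", "must be a proportion in [0, 1].")
  }
  check_distribution(ownership_subtype_probs, "ownership_subtype_probs",
                     c("public", "investor_chain", "gp_partnership",
                       "local_chain", "gp_owned"))
  priv <- sum(ownership_subtype_probs[setdiff(names(ownership_subtype_probs), "public")])
  if (abs(priv - share_private) > 1e-6) {
    abort_config("ownership_subtype_probs",
                 "private entries must sum to `share_private`.")
  }
  check_distribution(location_probs, "location_probs",
                     c("city", "commuting", "town", "rural"))
  if (!is_scalar_number(mean_permanent_staff) || mean_permanent_staff < 1) {
    abort_config("mean_permanent_staff", "must be at least 1.")
  }
  if (!is_scalar_number(temporary_share) || temporary_share < 0 || temporary_share >= 1) {
    abort_config("temporary_share", "must lie in [0, 1).")
  }
  check_distribution(temp_contract_probs, "temp_contract_probs",
                     setdiff(contract_types(), "permanent"))
  if (!setequal(names(exit_hazard_by_contract), contract_types())) {
    abort_config("exit_hazard_by_contract",
                 sprintf("must be named over {%s}.", paste(contract_types(), collapse = ", ")))
  }
  if (any(exit_hazard_by_contract < 0 | exit_hazard_by_contract > 1)) {
    abort_config("exit_hazard_by_contract", "entries must lie in [0, 1].")
  }
  temp_types <- setdiff(contract_types(), "permanent")
  if (any(exit_hazard_by_contract[temp_types] <= 0)) {
    abort_config("exit_hazard_by_contract",
                 "must be strictly positive for temporary contract types.")
  }
  if (!is_scalar_number(fixed_contract_mean_months) || fixed_contract_mean_months < 1) {
    abort_config("fixed_contract_mean_months", "must be at least 1 month.")
  }
  cd <- consult_days_per_month
  if (!is.list(cd) || !all(c("workdays", "intensity", "intensity_probs") %in% names(cd))) {
    abort_config("consult_days_per_month",
                 "must be a list with `workdays`, `intensity`, `intensity_probs`.")
  }
  if (!is_count(cd$workdays) || cd$workdays > 28) {
    abort_config("consult_days_per_month", "`workdays` must be a count of at most 28.")
  }
  if (any(cd$intensity < 0 | cd$intensity > 1)) {
    abort_config("consult_days_per_month", "`intensity` values must lie in [0, 1].")
  }
  check_distribution(cd$intensity_probs, "consult_days_per_month$intensity_probs")
  if (length(cd$intensity) != length(cd$intensity_probs)) {
    abort_config("consult_days_per_month",
                 "`intensity` and `intensity_probs` must have equal length.")
  }
  if (length(visits_per_day_iqr) != 2 || visits_per_day_iqr[1] > visits_per_day_iqr[2]) {
    abort_config("visits_per_day_iqr", "must be an ordered pair.")
  }
  if (!all(c("mean", "sd") %in% names(patients_per_practice)) ||
      patients_per_practice[["mean"]] <= 0 || patients_per_practice[["sd"]] < 0) {
    abort_config("patients_per_practice", "must provide a positive `mean` and non-negative `sd`.")
  }
  for (nm in c("morbidity_sd", "deprivation_sd")) {
    if (!is_scalar_number(get(nm)) || get(nm) < 0) abort_config(nm, "must be non-negative.")
  }
  if (!all(c("open", "close") %in% names(p_open_close)) ||
      any(p_open_close < 0 | p_open_close > 1)) {
    abort_config("p_open_close", "must give probabilities `open` and `close` in [0, 1].")
  }
  if (!is_scalar_number(ramp_up_months) || ramp_up_months < 0 ||
      ramp_up_months != as.integer(ramp_up_months)) {
    abort_config("ramp_up_months", "must be a non-negative integer.")
  }
  if (!is_scalar_number(leave_prob) || leave_prob < 0 || leave_prob > 1) {
    abort_config("leave_prob", "must be a probability in [0, 1].")
  }
  if (!is_scalar_number(leave_max_days) || leave_max_days < 1 || leave_max_days >= 365) {
    abort_config("leave_max_days",
                 "must be below 365 days so leaves do not split spells under the gap rule.")
  }
  if (!is.numeric(covariate_effects) ||
      !all(names(covariate_effects) %in% c("morbidity", "deprivation", "private"))) {
    abort_config("covariate_effects",
                 "must be a numeric vector named among {morbidity, deprivation, private}.")
  }
  eff <- c(morbidity = 0, deprivation = 0, private = 0)
  eff[names(covariate_effects)] <- covariate_effects

  structure(list(
    n_practices = as.integer(n_practices), years = as.integer(years),
    seed = as.integer(seed), share_private = share_private,
    ownership_subtype_probs = ownership_subtype_probs,
    location_probs = location_probs,
    mean_permanent_staff = mean_permanent_staff,
    temporary_share = temporary_share,
    temp_contract_probs = temp_contract_probs,
    exit_hazard_by_contract = exit_hazard_by_contract,
    fixed_contract_mean_months = fixed_contract_mean_months,
    consult_days_per_month = cd,
    visits_per_day_iqr = visits_per_day_iqr,
    patients_per_practice = patients_per_practice,
    morbidity_sd = morbidity_sd, deprivation_sd = deprivation_sd,
    p_open_close = p_open_close, ramp_up_months = as.integer(ramp_up_months),
    leave_prob = leave_prob, leave_max_days = leave_max_days,
    covariate_effects = eff), class = "registry_config")
}

#' Read a registry configuration from a YAML file
#'
#' Scalar and named-vector fields are taken as in [registry_config()]; named
#' YAML maps become named vectors.
#'
#' @param path Path to a YAML file whose keys are `registry_config()` arguments.
#' @return A validated `registry_config`.
#' @export
read_registry_config <- function(path) {
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), names(formals(registry_config)))
  if (length(unknown) > 0) {
    abort_config(unknown[1], "is not a recognised configuration field.")
  }
  vecs <- c("ownership_subtype_probs", "location_probs", "temp_contract_probs",
            "exit_hazard_by_contract", "patients_per_practice", "p_open_close",
            "covariate_effects")
  for (nm in intersect(vecs, names(raw))) raw[[nm]] <- unlist(raw[[nm]])
  if ("consult_days_per_month" %in% names(raw)) {
    raw$consult_days_per_month <- lapply(raw$consult_days_per_month, unlist)
  }
  do.call(registry_config, raw)
}
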