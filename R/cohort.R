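#' Identify index transplantations
#'
#' For each patient with at least one hospital stay in the study period
#' carrying a kidney-transplant procedure code, returns the admission date of
#' the earliest such stay as the index event. Later transplant-coded stays
#' are returned separately as retransplantation candidates (used by the
#' graft-loss proxy). Two transplant stays sharing an admission date collapse
#' to a single index event.
#'
#' @param bundle A `claims_bundle`.
#' @param study_period Two calendar years bounding admission dates considered
#'   for the index event.
#' @return A list with `index_events` (tibble: `patient_id`, `index_date`,
#'   `index_year`, `age_at_index`, `sex`) and `retransplants` (tibble:
#'   `patient_id`, `admission_date`).
#' @export
find_index <- function(bundle, study_period = c(2009, 2020)) {
  cc <- bundle$code_config
  lo <- as.Date(paste0(study_period[1], "-01-01"))
  hi <- as.Date(paste0(study_period[2], "-12-31"))
  tx <- bundle$stays |>
    dplyr::filter(codes_match(.data$procedure_codes, cc$transplant_procedure_codes))
  if (nrow(tx) == 0) {
    return(list(
      index_events = tibble::tibble(patient_id = character(),
                                    index_date = as.Date(character()),
                                    index_year = integer(),
                                    age_at_index = numeric(),
                                    sex = character()),
      retransplants = tibble::tibble(patient_id = character(),
                                     admission_date = as.Date(character()))))
  }
  index_events <- tx |>
    dplyr::filter(.data$admission_date >= lo, .data$admission_date <= hi) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(index_date = min(.data$admission_date), .groups = "drop") |>
    dplyr::left_join(bundle$patients, by = "patient_id") |>
    dplyr::mutate(
      index_year = as.integer(format(.data$index_date, "%Y")),
      age_at_index = floor(as.numeric(.data$index_date - .data$birth_date) /
                             cc$days_per_year)) |>
    dplyr::select("patient_id", "index_date", "index_year", "age_at_index", "sex")
  retransplants <- tx |>
    dplyr::inner_join(dplyr::select(index_events, "patient_id", "index_date"),
                      by = "patient_id") |>
    dplyr::filter(.data$admission_date > .data$index_date) |>
    dplyr::distinct(.data$patient_id, .data$admission_date)
  list(index_events = index_events, retransplants = retransplants)
}

# All claim dates (any table) per patient, used by the database-presence rule
# and the lost-to-follow-up rule.
all_claim_dates <- function(bundle) {
  dplyr::bind_rows(
    dplyr::select(bundle$stays, "patient_id", date = "admission_date"),
    dplyr::select(bundle$deliveries, "patient_id", date = "delivery_date"),
    dplyr::select(bundle$dialysis, "patient_id", date = "session_date"))
}

#' Apply the cohort eligibility rules
#'
#' Excludes patients aged under 18 at index, with undocumented sex, absent
#' from the database in the year before index (no claim of any type in
#' `[index - 365 d, index)`), or with inconsistent data (death before index,
#' or any claim dated after death). Each exclusion is attributed to the first
#' failing rule in that order, so the report counts partition the screened
#' patients.
#'
#' @param index_events Tibble from [find_index()].
#' @param bundle A `claims_bundle`.
#' @return A list with `cohort` (eligible index events) and `report` (tibble
#'   of screened / exclusion / eligible counts).
#' @export
apply_eligibility <- function(index_events, bundle) {
  cc <- bundle$code_config
  claims <- all_claim_dates(bundle)
  present <- index_events |>
    dplyr::inner_join(claims, by = "patient_id",
                      relationship = "one-to-many") |>
    dplyr::filter(.data$date >= .data$index_date - cc$lookback_days,
                  .data$date < .data$index_date) |>
    dplyr::distinct(.data$patient_id) |>
    dplyr::pull("patient_id")
  deaths <- bundle$patients |>
    dplyr::select("patient_id", "death_date")
  post_death <- claims |>
    dplyr::inner_join(deaths, by = "patient_id", relationship = "many-to-one") |>
    dplyr::filter(!is.na(.data$death_date), .data$date > .data$death_date) |>
    dplyr::distinct(.data$patient_id) |>
    dplyr::pull("patient_id")

  scored <- index_events |>
    dplyr::left_join(deaths, by = "patient_id") |>
    dplyr::mutate(
      reason = dplyr::case_when(
        .data$age_at_index < 18 ~ "under_18",
        is.na(.data$sex) | !(.data$sex %in% c("male", "female")) ~ "missing_sex",
        !(.data$patient_id %in% present) ~ "absent_prior_year",
        (!is.na(.data$death_date) & .data$death_date < .data$index_date) |
          .data$patient_id %in% post_death ~ "inconsistent",
        TRUE ~ "eligible"))
  cohort <- scored |>
    dplyr::filter(.data$reason == "eligible") |>
    dplyr::select(-"reason", -"death_date")
  reasons <- c("under_18", "missing_sex", "absent_prior_year", "inconsistent")
  report <- tibble::tibble(
    screened = nrow(scored),
    !!!setNames(lapply(reasons, function(r) sum(scored$reason == r)), reasons),
    eligible = nrow(cohort))
  list(cohort = cohort, report = report)
}

#' Flag baseline comorbidities and transplant history
#'
#' Comorbidity flags are raised when any configured code for the condition
#' appears in a stay diagnosis (principal or associated), a stay procedure,
#' or a delivery ATC code within the lookback window `[index - 365 d, index)`.
#' Transplant-history flags search the full historical window from the
#' configured history floor up to (but excluding) the index date:
#' `prior_kidney_transplant` (transplant procedure code before index),
#' `prior_other_transplant` (non-kidney organ transplant code before index),
#' `multiple_transplantation` (non-kidney organ transplant code during the
#' index stay itself), and `preemptive` (no dialysis session before index).
#'
#' @param cohort Tibble of eligible index events ([apply_eligibility()]).
#' @param bundle A `claims_bundle`.
#' @return Tibble with one row per cohort member and one logical column per
#'   flag.
#' @export
flag_baseline <- function(cohort, bundle) {
  cc <- bundle$code_config
  if (nrow(cohort) == 0) {
    return(dplyr::mutate(dplyr::select(cohort, "patient_id"), preemptive = logical()))
  }
  idx <- dplyr::select(cohort, "patient_id", "index_date")

  stay_codes <- bundle$stays |>
    dplyr::inner_join(idx, by = "patient_id", relationship = "many-to-one") |>
    dplyr::mutate(all_codes = paste(.data$procedure_codes,
                                    .data$principal_diagnosis,
                                    .data$associated_diagnoses, sep = "|"))
  lookback <- stay_codes |>
    dplyr::filter(.data$admission_date >= .data$index_date - cc$lookback_days,
                  .data$admission_date < .data$index_date)
  del_lb <- bundle$deliveries |>
    dplyr::inner_join(idx, by = "patient_id", relationship = "many-to-one") |>
    dplyr::filter(.data$delivery_date >= .data$index_date - cc$lookback_days,
                  .data$delivery_date < .data$index_date)

  out <- idx
  for (cond in names(cc$comorbidity_codelists)) {
    codes <- cc$comorbidity_codelists[[cond]]
    hit_stay <- lookback$patient_id[codes_match(lookback$all_codes, codes)]
    hit_del <- del_lb$patient_id[del_lb$atc_code %in% codes]
    out[[cond]] <- out$patient_id %in% c(hit_stay, hit_del)
  }

  hist <- stay_codes |>
    dplyr::filter(.data$admission_date >= cc$history_floor,
                  .data$admission_date < .data$index_date)
  prior_kidney <- hist$patient_id[codes_match(hist$all_codes,
                                              cc$transplant_procedure_codes)]
  prior_other <- hist$patient_id[codes_match(hist$all_codes,
                                             cc$other_organ_procedure_codes)]
  index_stays <- stay_codes |>
    dplyr::filter(.data$admission_date == .data$index_date)
  multi_organ <- index_stays$patient_id[codes_match(index_stays$all_codes,
                                                    cc$other_organ_procedure_codes)]
  pre_dial <- bundle$dialysis |>
    dplyr::inner_join(idx, by = "patient_id", relationship = "many-to-one") |>
    dplyr::filter(.data$session_date < .data$index_date) |>
    dplyr::distinct(.data$patient_id) |>
    dplyr::pull("patient_id")

  out |>
    dplyr::mutate(
      prior_kidney_transplant = .data$patient_id %in% prior_kidney,
      prior_other_transplant = .data$patient_id %in% prior_other,
      multiple_transplantation = .data$patient_id %in% multi_organ,
      preemptive = !(.data$patient_id %in% pre_dial)) |>
    dplyr::select(-"index_date")
}
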