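#' Date graft loss with the claims proxy
#'
#' Graft failure is not directly coded in claims; it is dated at the
#' earliest of three proxies: (a) the end of all-class immunosuppressive
#' coverage followed by more than `treatment_gap_days` days without any
#' delivery (dated at the coverage end); (b) the admission date of a
#' retransplantation stay; (c) the first session of a post-index dialysis
#' run spanning at least `dialysis_span_days` days with no inter-session gap
#' above `dialysis_gap_days` (dated at the run's first session). A silent
#' period cut short by death or by the administrative study end does not
#' qualify as a treatment gap.
#'
#' @param timeline Output of [build_timeline()].
#' @param retransplants Tibble `patient_id`, `admission_date` from
#'   [find_index()].
#' @param dialysis Dialysis-session tibble.
#' @param index_events Tibble with `patient_id`, `index_date`.
#' @param patients Patient tibble (for death dates).
#' @param study_end Administrative end of observation.
#' @param code_config A [code_config()].
#' @return Tibble `patient_id`, `graft_loss_day`, `graft_loss_reason`
#'   (`"treatment_gap"`, `"retransplant"` or `"dialysis_resumption"`), one
#'   row per patient with a detected loss.
#' @export
detect_graft_loss <- function(timeline, retransplants, dialysis, index_events,
                              patients, study_end = as.Date("2020-12-31"),
                              code_config = txtrace::code_config()) {
  cc <- code_config
  bounds <- index_events |>
    dplyr::select("patient_id", "index_date") |>
    dplyr::left_join(dplyr::select(patients, "patient_id", "death_date"),
                     by = "patient_id") |>
    dplyr::mutate(
      obs_end_day = pmin(as.integer(as.Date(study_end) - .data$index_date),
                         as.integer(.data$death_date - .data$index_date),
                         na.rm = TRUE))

  empty_cand <- tibble::tibble(patient_id = character(), day = integer(),
                               reason = character())

  # (a) treatment gap, on the union of coverage across all drug classes
  gap_cand <- if (nrow(timeline) == 0) empty_cand else timeline |>
    dplyr::arrange(.data$patient_id, .data$start_day, .data$end_day) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::mutate(run_end = cummax(.data$end_day),
                  new_iv = is.na(dplyr::lag(.data$run_end)) |
                    .data$start_day > dplyr::lag(.data$run_end),
                  iv = cumsum(.data$new_iv)) |>
    dplyr::group_by(.data$patient_id, .data$iv) |>
    dplyr::summarise(start_day = min(.data$start_day),
                     end_day = max(.data$end_day), .groups = "drop_last") |>
    dplyr::mutate(next_start = dplyr::lead(as.numeric(.data$start_day),
                                           default = Inf)) |>
    dplyr::ungroup() |>
    dplyr::inner_join(bounds, by = "patient_id") |>
    dplyr::filter(pmin(.data$next_start, .data$obs_end_day) - .data$end_day >
                    cc$treatment_gap_days) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::slice_min(.data$end_day, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::transmute(.data$patient_id, day = .data$end_day,
                     reason = "treatment_gap")

  # (b) retransplantation
  retx_cand <- if (nrow(retransplants) == 0) empty_cand else retransplants |>
    dplyr::inner_join(dplyr::select(bounds, "patient_id", "index_date"),
                      by = "patient_id") |>
    dplyr::mutate(day = as.integer(.data$admission_date - .data$index_date)) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::slice_min(.data$day, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::transmute(.data$patient_id, .data$day, reason = "retransplant")

  # (c) sustained dialysis resumption
  dial_cand <- if (nrow(dialysis) == 0) empty_cand else dialysis |>
    dplyr::inner_join(dplyr::select(bounds, "patient_id", "index_date"),
                      by = "patient_id", relationship = "many-to-one") |>
    dplyr::mutate(day = as.integer(.data$session_date - .data$index_date)) |>
    dplyr::filter(.data$day > 0) |>
    dplyr::distinct(.data$patient_id, .data$day) |>
    dplyr::arrange(.data$patient_id, .data$day) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::mutate(new_run = is.na(dplyr::lag(.data$day)) |
                    .data$day - dplyr::lag(.data$day) > cc$dialysis_gap_days,
                  run = cumsum(.data$new_run)) |>
    dplyr::group_by(.data$patient_id, .data$run) |>
    dplyr::summarise(first = dplyr::first(.data$day),
                     span = dplyr::last(.data$day) - dplyr::first(.data$day),
                     .groups = "drop") |>
    dplyr::filter(.data$span >= cc$dialysis_span_days) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::slice_min(.data$first, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::transmute(.data$patient_id, day = .data$first,
                     reason = "dialysis_resumption")

  dplyr::bind_rows(gap_cand, retx_cand, dial_cand) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::arrange(.data$day,
                   match(.data$reason, c("treatment_gap", "retransplant",
                                         "dialysis_resumption")),
                   .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::rename(graft_loss_day = "day", graft_loss_reason = "reason")
}

#' Assemble competing-risk outcome records
#'
#' One record per cohort member: follow-up time in years from index and an
#' event code (0 censored, 1 graft loss, 2 death), taking whichever of graft
#' loss, death and censoring occurred first. A graft loss strictly before
#' death wins; a same-day graft loss and death is coded as death. Patients
#' with no claim of any type for more than `lost_followup_days` before the
#' study end are censored at their last claim (lost to follow-up); everyone
#' else is censored at the study end.
#'
#' @param cohort Tibble with `patient_id`, `index_date`.
#' @param graft_losses Output of [detect_graft_loss()].
#' @param bundle The `claims_bundle` (death dates and claim dates).
#' @param study_end Administrative end of observation.
#' @param code_config A [code_config()].
#' @return Tibble `patient_id`, `time_years`, `event_code`, `event`,
#'   `graft_loss_reason`, `censor_reason`.
#' @export
assemble_outcomes <- function(cohort, graft_losses, bundle,
                              study_end = as.Date("2020-12-31"),
                              code_config = txtrace::code_config()) {
  cc <- code_config
  study_end <- as.Date(study_end)
  last_claim <- all_claim_dates(bundle) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(last_claim = max(.data$date), .groups = "drop")
  cohort |>
    dplyr::select("patient_id", "index_date") |>
    dplyr::left_join(dplyr::select(bundle$patients, "patient_id", "death_date"),
                     by = "patient_id") |>
    dplyr::left_join(graft_losses, by = "patient_id") |>
    dplyr::left_join(last_claim, by = "patient_id") |>
    dplyr::mutate(
      death_day = as.integer(.data$death_date - .data$index_date),
      end_day = as.integer(study_end - .data$index_date),
      ltfu = is.na(.data$death_day) &
        as.integer(study_end - .data$last_claim) > cc$lost_followup_days,
      censor_day = ifelse(.data$ltfu,
                          pmax(as.integer(.data$last_claim - .data$index_date), 0L),
                          .data$end_day),
      censor_reason = ifelse(.data$ltfu, "lost_to_followup", "study_end"),
      event = dplyr::case_when(
        !is.na(.data$graft_loss_day) &
          (is.na(.data$death_day) | .data$graft_loss_day < .data$death_day) &
          .data$graft_loss_day <= .data$censor_day ~ "graft_loss",
        !is.na(.data$death_day) & .data$death_day <= .data$end_day ~ "death",
        TRUE ~ "censored"),
      time_day = dplyr::case_when(
        .data$event == "graft_loss" ~ as.numeric(.data$graft_loss_day),
        .data$event == "death" ~ as.numeric(.data$death_day),
        TRUE ~ as.numeric(.data$censor_day)),
      time_years = .data$time_day / cc$days_per_year,
      event_code = unname(c(censored = 0L, graft_loss = 1L,
                            death = 2L)[.data$event]),
      graft_loss_reason = ifelse(.data$event == "graft_loss",
                                 .data$graft_loss_reason, "none"),
      censor_reason = ifelse(.data$event == "censored", .data$censor_reason,
                             "none")) |>
    dplyr::select("patient_id", "time_years", "event_code", "event",
                  "graft_loss_reason", "censor_reason")
}
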