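#' Default transplant-era buckets
#'
#' @return Named list of year ranges used for era-stratified treatment
#'   tables. The final study year is reported separately (follow-up in that
#'   year may be incomplete), so the default buckets stop in 2019.
#' @export
default_eras <- function() {
  list("2009-2011" = c(2009, 2011),
       "2012-2015" = c(2012, 2015),
       "2016-2019" = c(2016, 2019))
}

assign_era <- function(index_year, eras) {
  out <- rep(NA_character_, length(index_year))
  for (label in names(eras)) {
    rng <- eras[[label]]
    out[index_year >= rng[1] & index_year <= rng[2]] <- label
  }
  out
}

#' Cut ages into the standard adult age classes
#'
#' @param age Integer ages in completed years.
#' @return Character vector of [age_class_labels()] values.
#' @export
assign_age_class <- function(age) {
  cut(age, breaks = c(18, 30, 40, 50, 60, 70, Inf), right = FALSE,
      labels = age_class_labels()) |> as.character()
}

#' Treatment-use table by transplant era
#'
#' Counts and percentages of patients exposed at least once during
#' follow-up, per drug class group, per molecule, and per recognised
#' combination regimen, overall and by era of the index transplantation.
#' Denominators are all transplanted cohort members of the era; patients
#' whose index year falls outside the era buckets (the final, incompletely
#' reported study year) are excluded from this table.
#'
#' @param cohort Eligible index events with `index_year`.
#' @param timeline Output of [build_timeline()].
#' @param regimens Output of [detect_combinations()].
#' @param belatacept_calls Output of [detect_belatacept()].
#' @param code_config A [code_config()].
#' @param eras Named list of year ranges ([default_eras()]).
#' @return Tibble with columns `era`, `treatment`, `level` (`"any"`,
#'   `"class"`, `"molecule"`, `"combination"`), `n`, `denom`, `pct`.
#' @export
treatment_table <- function(cohort, timeline, regimens, belatacept_calls,
                            code_config = txtrace::code_config(),
                            eras = default_eras()) {
  members <- cohort |>
    dplyr::mutate(era = assign_era(.data$index_year, eras)) |>
    dplyr::filter(!is.na(.data$era)) |>
    dplyr::select("patient_id", "era")

  bela_pos <- belatacept_calls$patient_id[belatacept_calls$positive]
  mol_exposed <- timeline |>
    dplyr::distinct(.data$patient_id, .data$drug_class, .data$class_group)
  exposures <- dplyr::bind_rows(
    mol_exposed |>
      dplyr::transmute(.data$patient_id, treatment = .data$drug_class,
                       level = "molecule"),
    mol_exposed |>
      dplyr::distinct(.data$patient_id, treatment = .data$class_group) |>
      dplyr::mutate(level = "class"),
    tibble::tibble(patient_id = bela_pos, treatment = "belatacept",
                   level = "class"),
    regimens |>
      dplyr::filter(.data$recognized,
                    lengths(split_classes(.data$backbone)) > 1) |>
      dplyr::distinct(.data$patient_id, treatment = .data$backbone) |>
      dplyr::mutate(level = "combination")) |>
    dplyr::distinct()
  exposures <- dplyr::bind_rows(
    exposures,
    exposures |>
      dplyr::distinct(.data$patient_id) |>
      dplyr::mutate(treatment = "any_immunosuppressant", level = "any"))

  denom <- dplyr::bind_rows(members, dplyr::mutate(members, era = "overall")) |>
    dplyr::count(.data$era, name = "denom")
  counts <- exposures |>
    dplyr::inner_join(members, by = "patient_id",
                      relationship = "many-to-one") |>
    (\(d) dplyr::bind_rows(d, dplyr::mutate(d, era = "overall")))() |>
    dplyr::count(.data$era, .data$treatment, .data$level, name = "n")
  counts |>
    dplyr::left_join(denom, by = "era") |>
    dplyr::mutate(pct = 100 * .data$n / .data$denom) |>
    dplyr::arrange(.data$era, .data$level, dplyr::desc(.data$n))
}

#' Calendar-year prevalence of drug-class use
#'
#' A patient counts as using a molecule class in calendar year Y when at
#' least one delivery of that class is dated in Y; belatacept use counts
#' through the qualifying infusion stays of algorithm- or
#' retrocession-positive patients.
#'
#' @param deliveries Classified delivery tibble.
#' @param stays Stay tibble.
#' @param belatacept_calls Output of [detect_belatacept()].
#' @param code_config A [code_config()].
#' @return Tibble `year`, `treatment`, `level`, `n_patients`.
#' @export
yearly_prevalence <- function(deliveries, stays, belatacept_calls,
                              code_config = txtrace::code_config()) {
  if (!"drug_class" %in% names(deliveries)) {
    deliveries <- classify_deliveries(deliveries, code_config)
  }
  del <- deliveries |>
    dplyr::filter(.data$drug_class != "other") |>
    dplyr::mutate(year = as.integer(format(.data$delivery_date, "%Y")))
  bela_pos <- belatacept_calls$patient_id[belatacept_calls$positive]
  bela <- stays |>
    dplyr::filter(.data$patient_id %in% bela_pos, .data$is_chemo_delivery,
                  codes_match(paste(.data$principal_diagnosis,
                                    .data$associated_diagnoses, sep = "|"),
                              code_config$transplant_diagnosis_codes)) |>
    dplyr::mutate(year = as.integer(format(.data$admission_date, "%Y")))
  dplyr::bind_rows(
    del |> dplyr::distinct(.data$patient_id, .data$year,
                           treatment = .data$drug_class) |>
      dplyr::mutate(level = "molecule"),
    del |> dplyr::distinct(.data$patient_id, .data$year,
                           treatment = .data$class_group) |>
      dplyr::mutate(level = "class"),
    bela |> dplyr::distinct(.data$patient_id, .data$year) |>
      dplyr::mutate(treatment = "belatacept", level = "class"),
    bela |> dplyr::distinct(.data$patient_id, .data$year) |>
      dplyr::mutate(treatment = "belatacept", level = "molecule")) |>
    dplyr::distinct() |>
    dplyr::count(.data$year, .data$treatment, .data$level, name = "n_patients") |>
    dplyr::arrange(.data$year, .data$level, .data$treatment)
}

#' Cross-tabulate relay regimens
#'
#' Counts switch/add-on events by origin and destination class set,
#' separately for the first relay and subsequent relays, and reports the
#' fraction of cohort members who never changed regimen.
#'
#' @param switch_events Output of [detect_switches()].
#' @param cohort Cohort tibble (denominator for the never-switched fraction).
#' @return A list: `transitions` (tibble `from_classes`, `to_classes`,
#'   `kind`, `relay` (`"first"`/`"later"`), `n`), `n_patients`,
#'   `n_switchers`, `n_multi_switchers`, `never_switched_frac`.
#' @export
switch_matrix <- function(switch_events, cohort) {
  events <- switch_events |>
    dplyr::semi_join(cohort, by = "patient_id")
  transitions <- events |>
    dplyr::mutate(relay = ifelse(.data$order == 1, "first", "later")) |>
    dplyr::count(.data$from_classes, .data$to_classes, .data$kind, .data$relay,
                 name = "n") |>
    dplyr::arrange(dplyr::desc(.data$n))
  n_sw <- dplyr::n_distinct(events$patient_id)
  n_multi <- dplyr::n_distinct(events$patient_id[events$order > 1])
  list(transitions = transitions,
       n_patients = nrow(cohort),
       n_switchers = n_sw,
       n_multi_switchers = n_multi,
       never_switched_frac = if (nrow(cohort) > 0) 1 - n_sw / nrow(cohort) else NA_real_)
}

#' Run the full claims-analysis pipeline
#'
#' Orchestrates cohort construction, exposure phenotyping, outcome
#' derivation and survival estimation on a claims bundle, returning every
#' report table. The outcome table is evaluated at a landmark time on the
#' subcohort with enough potential follow-up (index before
#' `outcome_cutoff`), so that the landmark estimate is not dominated by
#' administrative censoring.
#'
#' @param bundle A `claims_bundle` (or a directory path readable by
#'   [read_bundle()]).
#' @param study_period Two calendar years bounding index events.
#' @param study_end Administrative end of observation.
#' @param eras Era buckets for the treatment table.
#' @param outcome_cutoff Index-date cutoff for the landmark outcome table.
#' @param at_years Landmark time in years.
#' @return An object of class `report_set`: a list with `cohort`,
#'   `eligibility`, `baseline`, `timeline`, `regimens`, `belatacept`,
#'   `switches`, `initial_regimens`, `outcomes`, `outcome_table`,
#'   `treatment`, `prevalence`, `switch_summary`, `metadata`.
#' @export
run_pipeline <- function(bundle, study_period = c(2009, 2020),
                         study_end = as.Date("2020-12-31"),
                         eras = default_eras(),
                         outcome_cutoff = as.Date("2015-01-01"),
                         at_years = 5) {
  if (is.character(bundle)) bundle <- read_bundle(bundle)
  cc <- bundle$code_config

  idx <- find_index(bundle, study_period)
  elig <- apply_eligibility(idx$index_events, bundle)
  cohort <- elig$cohort
  baseline <- flag_baseline(cohort, bundle)

  deliveries <- classify_deliveries(bundle$deliveries, cc)
  timeline <- build_timeline(deliveries, cohort, cc)
  bela <- detect_belatacept(bundle$stays, deliveries, cohort, cc)
  # make inferred belatacept exposure visible to the interval-based rules
  timeline <- dplyr::bind_rows(
    timeline, belatacept_episodes(bundle$stays, bela, cohort, cc)) |>
    dplyr::arrange(.data$patient_id, .data$drug_class, .data$start_day)
  regimens <- detect_combinations(timeline, cc)
  switches <- detect_switches(timeline, cc)
  initial <- initial_regimen(timeline, bela, cohort, cc)

  losses <- detect_graft_loss(timeline, idx$retransplants, bundle$dialysis,
                              cohort, bundle$patients, study_end, cc)
  outcomes <- assemble_outcomes(cohort, losses, bundle, study_end, cc) |>
    dplyr::left_join(dplyr::select(cohort, "patient_id", "age_at_index",
                                   "index_date", "index_year"),
                     by = "patient_id") |>
    dplyr::mutate(age_class = assign_age_class(.data$age_at_index))

  landmark <- dplyr::filter(outcomes, .data$index_date < as.Date(outcome_cutoff))
  outcome_table <- if (nrow(landmark) > 0) {
    stratified_outcomes(landmark, strata = "age_class", at_years = at_years)
  } else {
    tibble::tibble()
  }

  structure(list(
    cohort = cohort,
    eligibility = elig$report,
    baseline = baseline,
    timeline = timeline,
    regimens = regimens,
    belatacept = bela,
    switches = switches,
    initial_regimens = initial,
    outcomes = outcomes,
    outcome_table = outcome_table,
    treatment = treatment_table(cohort, timeline, regimens, bela, cc, eras),
    prevalence = yearly_prevalence(deliveries, bundle$stays, bela, cc),
    switch_summary = switch_matrix(switches, cohort),
    metadata = list(
      package_version = as.character(utils::packageVersion("txtrace")),
      config_hash = rlang::hash(cc),
      study_period = study_period,
      study_end = as.character(study_end),
      outcome_cutoff = as.character(outcome_cutoff),
      at_years = at_years,
      n_screened = elig$report$screened,
      n_cohort = nrow(cohort))
  ), class = "report_set")
}

#' @export
print.report_set <- function(x, ...) {
  cat("<report_set>\n")
  cat("  screened:", x$metadata$n_screened, " cohort:", x$metadata$n_cohort, "\n")
  cat("  graft losses:", sum(x$outcomes$event_code == 1),
      " deaths:", sum(x$outcomes$event_code == 2), "\n")
  if (nrow(x$outcome_table) > 0) {
    all_row <- x$outcome_table[x$outcome_table$stratum == "all", ]
    cat(sprintf("  %g-year overall survival %.3f [%.3f-%.3f], graft survival %.3f [%.3f-%.3f] (n=%d)\n",
                x$metadata$at_years, all_row$surv, all_row$surv_low,
                all_row$surv_high, all_row$graft_surv, all_row$graft_surv_low,
                all_row$graft_surv_high, all_row$n))
  }
  cat("  switchers:", x$switch_summary$n_switchers, "of",
      x$switch_summary$n_patients, "\n")
  invisible(x)
}

#' Write a report set to disk
#'
#' Writes each table as CSV plus a JSON metadata/summary file.
#'
#' @param report A `report_set`.
#' @param path Output directory.
#' @return Invisibly, the directory path.
#' @export
write_report_set <- function(report, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  tables <- c("cohort", "eligibility", "baseline", "timeline", "regimens",
              "belatacept", "switches", "initial_regimens", "outcomes",
              "outcome_table", "treatment", "prevalence")
  for (tb in tables) {
    obj <- report[[tb]]
    if (is.data.frame(obj)) {
      attr(obj, "curves") <- NULL
      readr::write_csv(obj, file.path(path, paste0(tb, ".csv")), na = "")
    }
  }
  readr::write_csv(report$switch_summary$transitions,
                   file.path(path, "switch_transitions.csv"), na = "")
  jsonlite::write_json(
    c(report$metadata,
      report$switch_summary[c("n_patients", "n_switchers", "n_multi_switchers",
                              "never_switched_frac")]),
    file.path(path, "summary.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(path)
}
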