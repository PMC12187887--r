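#' Assemble and validate a claims bundle
#'
#' A claims bundle holds the four raw claims tables the pipeline consumes,
#' plus the [code_config()] interpreting them. Multi-valued code fields
#' (procedure codes, associated diagnoses) are stored as `|`-separated
#' strings so every table stays a plain tibble.
#'
#' @param patients Tibble with columns `patient_id`, `birth_date`, `sex`
#'   (`"male"`, `"female"` or `"missing"`), `death_date` (`NA` if alive).
#' @param stays Tibble with columns `patient_id`, `admission_date`,
#'   `discharge_date`, `procedure_codes`, `principal_diagnosis`,
#'   `associated_diagnoses`, `is_chemo_delivery` (logical; stay coded as a
#'   chemotherapy-delivery session for a non-tumoral disease).
#' @param deliveries Tibble with columns `patient_id`, `delivery_date`,
#'   `atc_code`, `presentation_id`.
#' @param dialysis Tibble with columns `patient_id`, `session_date`.
#' @param code_config A [code_config()].
#' @return An object of class `claims_bundle`.
#' @export
claims_bundle <- function(patients, stays, deliveries, dialysis,
                          code_config = txtrace::code_config()) {
  b <- structure(list(
    patients = coerce_patients(patients),
    stays = coerce_stays(stays),
    deliveries = coerce_deliveries(deliveries),
    dialysis = coerce_dialysis(dialysis),
    code_config = code_config
  ), class = "claims_bundle")
  problems <- validate_bundle(b)
  if (length(problems) > 0) {
    stop("invalid claims bundle:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  b
}

empty_patients <- function() {
  tibble::tibble(patient_id = character(), birth_date = as.Date(character()),
                 sex = character(), death_date = as.Date(character()))
}

empty_stays <- function() {
  tibble::tibble(patient_id = character(),
                 admission_date = as.Date(character()),
                 discharge_date = as.Date(character()),
                 procedure_codes = character(), principal_diagnosis = character(),
                 associated_diagnoses = character(), is_chemo_delivery = logical())
}

empty_deliveries <- function() {
  tibble::tibble(patient_id = character(), delivery_date = as.Date(character()),
                 atc_code = character(), presentation_id = character())
}

empty_dialysis <- function() {
  tibble::tibble(patient_id = character(), session_date = as.Date(character()))
}

coerce_patients <- function(x) {
  x <- tibble::as_tibble(x)
  need <- names(empty_patients())
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0) {
    stop("patients table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  dplyr::mutate(x[need],
                patient_id = as.character(.data$patient_id),
                birth_date = as.Date(.data$birth_date),
                sex = as.character(.data$sex),
                death_date = as.Date(.data$death_date))
}

coerce_stays <- function(x) {
  x <- tibble::as_tibble(x)
  need <- names(empty_stays())
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0) {
    stop("stays table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  dplyr::mutate(x[need],
                patient_id = as.character(.data$patient_id),
                admission_date = as.Date(.data$admission_date),
                discharge_date = as.Date(.data$discharge_date),
                procedure_codes = dplyr::coalesce(as.character(.data$procedure_codes), ""),
                principal_diagnosis = dplyr::coalesce(as.character(.data$principal_diagnosis), ""),
                associated_diagnoses = dplyr::coalesce(as.character(.data$associated_diagnoses), ""),
                is_chemo_delivery = as.logical(.data$is_chemo_delivery))
}

coerce_deliveries <- function(x) {
  x <- tibble::as_tibble(x)
  need <- names(empty_deliveries())
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0) {
    stop("deliveries table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  dplyr::mutate(x[need],
                patient_id = as.character(.data$patient_id),
                delivery_date = as.Date(.data$delivery_date),
                atc_code = as.character(.data$atc_code),
                presentation_id = dplyr::coalesce(as.character(.data$presentation_id), ""))
}

coerce_dialysis <- function(x) {
  x <- tibble::as_tibble(x)
  need <- names(empty_dialysis())
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0) {
    stop("dialysis table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  dplyr::mutate(x[need],
                patient_id = as.character(.data$patient_id),
                session_date = as.Date(.data$session_date))
}

#' Validate a claims bundle against its invariants
#'
#' Checks patient_id uniqueness, date ordering (death after birth, discharge
#' on/after admission), non-empty ATC codes, parseable dates, and referential
#' integrity (every patient_id in the event tables must exist in `patients`).
#'
#' @param bundle A `claims_bundle` (validation is also run by the constructor).
#' @return Character vector of row-numbered problem descriptions; empty when
#'   the bundle is valid.
#' @export
validate_bundle <- function(bundle) {
  problems <- character()
  note <- function(table, rows, what) {
    if (length(rows) > 0) {
      sprintf("%s row %d: %s", table, rows, what)
    } else {
      character()
    }
  }
  p <- bundle$patients
  dup <- which(duplicated(p$patient_id))
  problems <- c(problems, note("patients", dup, "duplicate patient_id"))
  problems <- c(problems, note("patients", which(is.na(p$patient_id) | p$patient_id == ""),
                               "missing patient_id"))
  problems <- c(problems, note("patients", which(is.na(p$birth_date)), "unparseable birth_date"))
  bad_death <- which(!is.na(p$death_date) & !is.na(p$birth_date) & p$death_date < p$birth_date)
  problems <- c(problems, note("patients", bad_death, "death_date before birth_date"))

  s <- bundle$stays
  problems <- c(problems, note("stays", which(is.na(s$admission_date)), "unparseable admission_date"))
  problems <- c(problems, note("stays", which(is.na(s$discharge_date)), "unparseable discharge_date"))
  bad_order <- which(!is.na(s$admission_date) & !is.na(s$discharge_date) &
                       s$discharge_date < s$admission_date)
  problems <- c(problems, note("stays", bad_order, "discharge_date before admission_date"))

  d <- bundle$deliveries
  problems <- c(problems, note("deliveries", which(is.na(d$delivery_date)), "unparseable delivery_date"))
  problems <- c(problems, note("deliveries", which(is.na(d$atc_code) | d$atc_code == ""),
                               "empty atc_code"))

  y <- bundle$dialysis
  problems <- c(problems, note("dialysis", which(is.na(y$session_date)), "unparseable session_date"))

  known <- p$patient_id
  for (tab in c("stays", "deliveries", "dialysis")) {
    orphan <- which(!(bundle[[tab]]$patient_id %in% known))
    problems <- c(problems, note(tab, orphan, "patient_id not present in patients table"))
  }
  problems
}

#' @export
print.claims_bundle <- function(x, ...) {
  cat("<claims_bundle>\n")
  cat(sprintf("  %d patients, %d stays, %d deliveries, %d dialysis sessions\n",
              nrow(x$patients), nrow(x$stays), nrow(x$deliveries), nrow(x$dialysis)))
  invisible(x)
}

bundle_files <- c(patients = "patients.csv", stays = "stays.csv",
                  deliveries = "deliveries.csv", dialysis = "dialysis.csv")

#' Read a claims bundle from a directory of CSV files
#'
#' Expects `patients.csv`, `stays.csv`, `deliveries.csv` and `dialysis.csv`
#' (UTF-8, comma-separated, ISO-8601 dates, header row). Rows violating the
#' bundle invariants are reported with their row numbers; a missing file or
#' an orphan patient_id is fatal.
#'
#' @param path Directory holding the four CSVs.
#' @param code_config A [code_config()] attached to the bundle.
#' @return A `claims_bundle`.
#' @export
read_bundle <- function(path, code_config = txtrace::code_config()) {
  for (f in bundle_files) {
    if (!file.exists(file.path(path, f))) {
      stop("missing input file: ", file.path(path, f), call. = FALSE)
    }
  }
  read_one <- function(file, coltypes) {
    readr::read_csv(file.path(path, file), col_types = coltypes,
                    na = c("", "NA"), progress = FALSE)
  }
  patients <- read_one("patients.csv", readr::cols(
    patient_id = readr::col_character(), birth_date = readr::col_date(),
    sex = readr::col_character(), death_date = readr::col_date()))
  stays <- read_one("stays.csv", readr::cols(
    patient_id = readr::col_character(), admission_date = readr::col_date(),
    discharge_date = readr::col_date(), procedure_codes = readr::col_character(),
    principal_diagnosis = readr::col_character(),
    associated_diagnoses = readr::col_character(),
    is_chemo_delivery = readr::col_logical()))
  deliveries <- read_one("deliveries.csv", readr::cols(
    patient_id = readr::col_character(), delivery_date = readr::col_date(),
    atc_code = readr::col_character(), presentation_id = readr::col_character()))
  dialysis <- read_one("dialysis.csv", readr::cols(
    patient_id = readr::col_character(), session_date = readr::col_date()))
  claims_bundle(patients, stays, deliveries, dialysis, code_config)
}

#' Write a claims bundle to a directory of CSV files
#'
#' Emits the four CSVs in the documented dialect with deterministic row order
#' (patient_id, then date).
#'
#' @param bundle A `claims_bundle`.
#' @param path Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_bundle <- function(bundle, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create output directory: ", path, call. = FALSE)
  out <- file.path(path, unname(bundle_files))
  readr::write_csv(dplyr::arrange(bundle$patients, .data$patient_id),
                   file.path(path, "patients.csv"), na = "")
  readr::write_csv(dplyr::arrange(bundle$stays, .data$patient_id, .data$admission_date),
                   file.path(path, "stays.csv"), na = "")
  readr::write_csv(dplyr::arrange(bundle$deliveries, .data$patient_id, .data$delivery_date,
                                  .data$atc_code),
                   file.path(path, "deliveries.csv"), na = "")
  readr::write_csv(dplyr::arrange(bundle$dialysis, .data$patient_id, .data$session_date),
                   file.path(path, "dialysis.csv"), na = "")
  invisible(out)
}

#' Classify pharmacy deliveries into drug classes
#'
#' Adds `drug_class` (molecule level) and `class_group` (rollup) columns by
#' looking each ATC code up in the configuration map. Unknown codes classify
#' as `other` and never fail.
#'
#' @param deliveries Delivery tibble (`atc_code` column required).
#' @param code_config A [code_config()].
#' @return The input tibble with `drug_class` and `class_group` appended.
#' @export
classify_deliveries <- function(deliveries, code_config = txtrace::code_config()) {
  cls <- classify_atc(deliveries$atc_code, code_config)
  dplyr::mutate(tibble::as_tibble(deliveries),
                drug_class = cls, class_group = roll_up_class(cls))
}

#' @rdname classify_deliveries
#' @param atc_code Character vector of ATC codes.
#' @export
classify_atc <- function(atc_code, code_config = txtrace::code_config()) {
  out <- unname(code_config$drug_class_map[atc_code])
  out[is.na(out)] <- "other"
  out
}

# Vectorised membership test for |-separated code fields.
codes_match <- function(field, codeset) {
  if (length(codeset) == 0) return(rep(FALSE, length(field)))
  vapply(strsplit(dplyr::coalesce(field, ""), "|", fixed = TRUE),
         function(cs) any(cs %in% codeset), logical(1))
}
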