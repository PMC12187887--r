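#' Drug classes recognised by the exposure engine
#'
#' Molecule-level classes used to label pharmacy deliveries, and the
#' class-group rollups used for regimen recognition. `CNI` groups the
#' calcineurin inhibitors (tacrolimus, ciclosporin), `antimetabolite`
#' groups mycophenolic acid and azathioprine, and `mTORi` groups
#' everolimus and sirolimus.
#'
#' @return `drug_classes()` and `class_groups()` return character vectors.
#' @export
drug_classes <- function() {
  c("tacrolimus", "ciclosporin", "mycophenolic_acid", "azathioprine",
    "everolimus", "sirolimus", "corticosteroid", "belatacept", "other")
}

#' @rdname drug_classes
#' @export
class_groups <- function() {
  c("CNI", "antimetabolite", "mTORi", "corticosteroid", "belatacept", "other")
}

#' Map molecule classes to class groups
#'
#' @param classes Character vector of molecule-level classes.
#' @return Character vector of class groups, same length.
#' @export
roll_up_class <- function(classes) {
  map <- c(tacrolimus = "CNI", ciclosporin = "CNI",
           mycophenolic_acid = "antimetabolite", azathioprine = "antimetabolite",
           everolimus = "mTORi", sirolimus = "mTORi",
           corticosteroid = "corticosteroid", belatacept = "belatacept",
           other = "other")
  out <- unname(map[classes])
  out[is.na(out)] <- "other"
  out
}

default_drug_class_map <- function() {
  c("L04AD02" = "tacrolimus",
    "L04AD01" = "ciclosporin",
    "L04AA06" = "mycophenolic_acid",
    "L04AX01" = "azathioprine",
    "L04AA18" = "everolimus",
    "L04AA10" = "sirolimus",
    "H02AB06" = "corticosteroid",
    "H02AB07" = "corticosteroid",
    "L04AA28" = "belatacept")
}

default_comorbidity_codelists <- function() {
  # ICD-10 chapter-level stand-ins; the real national codelists are not public,
  # so these defaults exist to exercise the machinery and are fully replaceable.
  list(
    hypertension            = c("I10", "I11", "I12", "I13", "I15"),
    dyslipidemia            = c("E78"),
    diabetes                = c("E10", "E11", "E12", "E13", "E14"),
    ischemic_heart_disease  = c("I20", "I21", "I22", "I24", "I25"),
    obesity_bariatric       = c("E66", "HFQC001"),
    heart_failure           = c("I50"),
    peripheral_artery_disease = c("I70", "I73"),
    malnutrition            = c("E40", "E41", "E42", "E43", "E44", "E46"),
    stroke                  = c("I60", "I61", "I63", "I64")
  )
}

default_recognized_regimens <- function() {
  # Recognised multi-drug maintenance backbones (corticosteroids never affect
  # recognition and may accompany any of these).
  list(
    c("CNI", "antimetabolite"),
    c("CNI", "mTORi"),
    c("mTORi", "antimetabolite"),
    c("CNI", "mTORi", "antimetabolite"),
    c("belatacept", "antimetabolite")
  )
}

#' Code-list and window configuration
#'
#' Bundles every code list and day-count parameter used by the phenotyping
#' rules. All windows follow the convention that a "month" is 30 days and
#' "three months" is 91 days; intervals are half-open `[start, end)` in days.
#'
#' @param transplant_procedure_codes Procedure codes identifying a kidney
#'   transplantation stay (defaults `JAE003`, `HNEA002`).
#' @param other_organ_procedure_codes Procedure codes for non-kidney organ
#'   transplantation, used for multi-organ and prior-transplant history flags.
#' @param transplant_diagnosis_codes Diagnosis codes marking a stay as related
#'   to kidney transplantation (used by the belatacept infusion algorithm).
#' @param drug_class_map Named character vector mapping ATC codes to the
#'   molecule classes of [drug_classes()]. Unmapped codes classify as `other`.
#' @param comorbidity_codelists Named list of code vectors; a flag is raised
#'   when any listed code appears in the lookback window (diagnoses, ATC codes
#'   and procedures are all searched).
#' @param recognized_regimens List of character vectors of class groups; a
#'   multi-drug overlap only counts as a combination regimen when its
#'   non-steroid class-group set is listed here.
#' @param coverage_days Days of drug coverage granted by one delivery.
#' @param merge_gap_days Coverage intervals separated by at most this many
#'   days are merged into one episode.
#' @param treatment_gap_days A gap in all-class immunosuppressive coverage
#'   strictly longer than this signals graft loss.
#' @param dialysis_span_days Minimum span of a post-transplant dialysis run to
#'   qualify as graft loss.
#' @param dialysis_gap_days Maximum gap between successive sessions of one
#'   dialysis run.
#' @param belatacept_window_days Window (days, inclusive) for the three
#'   infusion stays and the companion mTORi/antimetabolite delivery.
#' @param belatacept_min_stays Minimum number of qualifying infusion stays.
#' @param cni_free_window Half-open day interval after the index infusion
#'   hospitalization during which any CNI delivery vetoes the call (the
#'   "fourth month", days 91-120 inclusive).
#' @param lookback_days Comorbidity lookback before the index date.
#' @param history_floor Earliest date with usable history (claims before it
#'   are ignored for transplant-history flags).
#' @param initial_window_days Post-index window defining the initial regimen;
#'   new drug classes starting after it are switch/add-on candidates.
#' @param lost_followup_days All-claim silence longer than this before study
#'   end censors the patient at their last claim (lost to follow-up).
#' @param days_per_year Day-to-year conversion factor.
#' @return An object of class `code_config` (a named list).
#' @examples
#' cfg <- code_config()
#' cfg$treatment_gap_days
#' @export
code_config <- function(transplant_procedure_codes = c("JAE003", "HNEA002"),
                        other_organ_procedure_codes = c("DZEA002", "EZEA001", "GZFA001"),
                        transplant_diagnosis_codes = c("Z940", "T861"),
                        drug_class_map = default_drug_class_map(),
                        comorbidity_codelists = default_comorbidity_codelists(),
                        recognized_regimens = default_recognized_regimens(),
                        coverage_days = 30,
                        merge_gap_days = 31,
                        treatment_gap_days = 91,
                        dialysis_span_days = 91,
                        dialysis_gap_days = 45,
                        belatacept_window_days = 90,
                        belatacept_min_stays = 3,
                        cni_free_window = c(91, 121),
                        lookback_days = 365,
                        history_floor = as.Date("2008-01-01"),
                        initial_window_days = 90,
                        lost_followup_days = 365,
                        days_per_year = 365.25) {
  stopifnot(is.character(drug_class_map), !is.null(names(drug_class_map)))
  bad <- setdiff(unique(unname(drug_class_map)), drug_classes())
  if (length(bad) > 0) {
    stop("drug_class_map contains unknown classes: ", paste(bad, collapse = ", "))
  }
  for (reg in recognized_regimens) {
    if (!all(reg %in% class_groups())) {
      stop("recognized_regimens references undefined class groups: ",
           paste(setdiff(reg, class_groups()), collapse = ", "))
    }
  }
  stopifnot(coverage_days > 0, merge_gap_days >= 0, treatment_gap_days > 0,
            length(cni_free_window) == 2, cni_free_window[1] < cni_free_window[2])
  structure(list(
    transplant_procedure_codes = transplant_procedure_codes,
    other_organ_procedure_codes = other_organ_procedure_codes,
    transplant_diagnosis_codes = transplant_diagnosis_codes,
    drug_class_map = drug_class_map,
    comorbidity_codelists = comorbidity_codelists,
    recognized_regimens = recognized_regimens,
    coverage_days = coverage_days,
    merge_gap_days = merge_gap_days,
    treatment_gap_days = treatment_gap_days,
    dialysis_span_days = dialysis_span_days,
    dialysis_gap_days = dialysis_gap_days,
    belatacept_window_days = belatacept_window_days,
    belatacept_min_stays = belatacept_min_stays,
    cni_free_window = cni_free_window,
    lookback_days = lookback_days,
    history_floor = as.Date(history_floor),
    initial_window_days = initial_window_days,
    lost_followup_days = lost_followup_days,
    days_per_year = days_per_year
  ), class = "code_config")
}

#' @export
print.code_config <- function(x, ...) {
  cat("<code_config>\n")
  cat("  transplant procedures:", paste(x$transplant_procedure_codes, collapse = ", "), "\n")
  cat("  mapped ATC codes:", length(x$drug_class_map), "\n")
  cat("  comorbidity code lists:", paste(names(x$comorbidity_codelists), collapse = ", "), "\n")
  cat("  coverage", x$coverage_days, "d | merge gap", x$merge_gap_days,
      "d | treatment gap >", x$treatment_gap_days, "d\n")
  invisible(x)
}

#' Write / read a code configuration as JSON
#'
#' @param config A [code_config()] object.
#' @param path File path.
#' @return `read_code_config()` returns a `code_config`.
#' @export
write_code_config <- function(config, path) {
  x <- unclass(config)
  x$history_floor <- format(x$history_floor)
  x$drug_class_map <- as.list(x$drug_class_map)  # keep names in JSON
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_code_config
#' @export
read_code_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$drug_class_map <- unlist(x$drug_class_map)
  x$comorbidity_codelists <- lapply(x$comorbidity_codelists, as.character)
  x$recognized_regimens <- lapply(x$recognized_regimens, as.character)
  do.call(code_config, x)
}
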