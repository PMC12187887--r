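#' Configuration for the synthetic claims generator
#'
#' The generator emulates a national claims extract for an incident kidney
#' transplant cohort: one transplant hospitalization per patient, roughly
#' monthly community-pharmacy deliveries of the maintenance regimen,
#' hospital infusion stays (coded as chemotherapy delivery with a transplant
#' diagnosis) for belatacept-treated patients, dialysis resumption after
#' graft failure, and death dates. Cause-specific hazards for graft failure
#' and death are constant (exponential), which keeps closed-form survival
#' quantities available for validation.
#'
#' @param n_patients Number of patients.
#' @param index_period Two calendar years; index transplant dates are uniform
#'   over this period.
#' @param study_end Administrative end of observation.
#' @param admin_censor_years Cap on per-patient follow-up, in years.
#' @param age_class_weights Probabilities over the six adult age classes
#'   `18-29, 30-39, 40-49, 50-59, 60-69, 70+` (defaults echo the age mix of a
#'   French national transplant cohort).
#' @param sex_split Fraction male.
#' @param lambda_death,lambda_graft Constant cause-specific hazards per year.
#'   `lambda_death` may be a single value or one value per age class. Defaults
#'   are calibrated so that 5-year overall survival is 0.890 and the 5-year
#'   graft-failure cumulative incidence is 0.150.
#' @param regimen_mix Named probability vector over initial maintenance
#'   regimens; names are `+`-joined molecule classes.
#' @param belatacept_fraction Fraction of patients whose maintenance regimen
#'   is belatacept-based from the outset.
#' @param switch_rate Per-year intensity of regimen changes; successive
#'   changes are at least `min_switch_gap_days` apart.
#' @param min_switch_gap_days Floor on the gap between consecutive regimen
#'   changes.
#' @param delivery_interval_days Cadence of pharmacy deliveries (and of
#'   belatacept infusion stays).
#' @param dialysis_interval_days Cadence of dialysis sessions (pre-transplant
#'   and after graft failure).
#' @param preemptive_fraction Fraction transplanted without prior dialysis.
#' @param hypertension_prevalence Fraction given a pre-index stay carrying a
#'   hypertension diagnosis code.
#' @param missed_delivery_prob,extra_chemo_stay_rate,delivery_delay_max_days
#'   Noise knobs, all zero by default: per-delivery drop probability,
#'   expected number of non-qualifying chemotherapy stays per patient, and
#'   maximum random delay (days) added to each delivery.
#' @param underage_fraction,missing_sex_fraction,absent_prior_fraction
#'   Ineligibility knobs (default zero): fractions of patients generated
#'   under 18 at index, with undocumented sex, or with no claims in the year
#'   before index.
#' @param seed Integer seed; fully determines the output.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_patients = 1000,
                       index_period = c(2009, 2020),
                       study_end = as.Date("2020-12-31"),
                       admin_censor_years = 12,
                       age_class_weights = c(`18-29` = 0.068, `30-39` = 0.124,
                                             `40-49` = 0.191, `50-59` = 0.249,
                                             `60-69` = 0.247, `70+` = 0.121),
                       sex_split = 0.627,
                       lambda_death = 0.023306,
                       lambda_graft = 0.034550,
                       regimen_mix = c(
                         "tacrolimus+mycophenolic_acid+corticosteroid" = 0.66,
                         "ciclosporin+mycophenolic_acid+corticosteroid" = 0.14,
                         "tacrolimus+everolimus+corticosteroid" = 0.06,
                         "everolimus+mycophenolic_acid+corticosteroid" = 0.06,
                         "tacrolimus+mycophenolic_acid" = 0.08),
                       belatacept_fraction = 0.039,
                       switch_rate = 0.065,
                       min_switch_gap_days = 365,
                       delivery_interval_days = 30,
                       dialysis_interval_days = 30,
                       preemptive_fraction = 0.132,
                       hypertension_prevalence = 0.92,
                       missed_delivery_prob = 0,
                       extra_chemo_stay_rate = 0,
                       delivery_delay_max_days = 0,
                       underage_fraction = 0,
                       missing_sex_fraction = 0,
                       absent_prior_fraction = 0,
                       seed = 1L) {
  stopifnot(n_patients >= 0, length(index_period) == 2,
            all(lambda_death >= 0), all(lambda_graft >= 0),
            length(age_class_weights) == 6)
  if (abs(sum(age_class_weights) - 1) > 1e-8) {
    stop("age_class_weights must sum to 1")
  }
  if (abs(sum(regimen_mix) - 1) > 1e-8) {
    stop("regimen_mix must sum to 1")
  }
  if (!length(lambda_death) %in% c(1L, 6L)) {
    stop("lambda_death must have length 1 or one value per age class")
  }
  structure(as.list(environment()), class = "sim_config")
}

age_class_bounds <- list(`18-29` = c(18, 29), `30-39` = c(30, 39),
                         `40-49` = c(40, 49), `50-59` = c(50, 59),
                         `60-69` = c(60, 69), `70+` = c(70, 85))

#' Age class labels used throughout the package
#' @return Character vector of the six adult age-class labels.
#' @export
age_class_labels <- function() names(age_class_bounds)

#' Sample competing-risk event times under constant cause-specific hazards
#'
#' Latent-time-free sampler: the first-event time is exponential with rate
#' `lambda_graft + lambda_death`; the event type is graft failure with
#' probability `lambda_graft / (lambda_graft + lambda_death)`. Times beyond
#' `horizon` are censored at the horizon.
#'
#' @param n Number of draws.
#' @param lambda_graft,lambda_death Cause-specific hazards per year (scalars
#'   or length-`n` vectors).
#' @param horizon Administrative censoring time in years (scalar or
#'   length-`n`).
#' @return Tibble with columns `event` (`"censored"`, `"graft_loss"`,
#'   `"death"`) and `time` (years).
#' @examples
#' set.seed(1)
#' sample_event_times(5, 0.0345, 0.0233, 12)
#' @export
sample_event_times <- function(n, lambda_graft, lambda_death, horizon) {
  total <- lambda_graft + lambda_death
  total <- rep_len(total, n)
  lg <- rep_len(lambda_graft, n)
  horizon <- rep_len(horizon, n)
  time <- ifelse(total > 0, rexp(n, pmax(total, .Machine$double.xmin)), Inf)
  type <- ifelse(runif(n) * total < lg, "graft_loss", "death")
  censored <- time > horizon | total == 0
  tibble::tibble(event = ifelse(censored, "censored", type),
                 time = pmin(time, horizon))
}

# Relay regimens must add at least one new non-steroid molecule class,
# otherwise the change is invisible in claims.
relay_candidates <- function(current_classes, mix_names) {
  cur <- setdiff(current_classes, "corticosteroid")
  keep <- vapply(split_classes(mix_names), function(cl) {
    length(setdiff(setdiff(cl, "corticosteroid"), cur)) > 0
  }, logical(1))
  mix_names[keep]
}

#' Generate a synthetic claims bundle with ground truth
#'
#' Produces a [claims_bundle()] plus the per-patient truth that generated it
#' (index date, regimen timeline, true belatacept exposure, true event type
#' and time). With the noise knobs at zero, the claim stream is constructed
#' so that the phenotyping rules can recover the truth exactly: belatacept
#' segments always produce three qualifying infusion stays, true graft
#' losses always leave a detectable treatment gap and dialysis run, and
#' graft failures too close to the censoring horizon for the 3-month-gap
#' proxy to observe are emitted as censored in both truth and claims.
#'
#' @param config A [sim_config()].
#' @param code_config A [code_config()]; codes in the bundle are drawn from
#'   its code lists.
#' @return A list with elements `bundle` (a `claims_bundle`), `truth` (tibble,
#'   one row per patient) and `truth_timeline` (tibble of true regimen
#'   segments in days from index).
#' @examples
#' sim <- simulate_claims(sim_config(n_patients = 20, seed = 7))
#' sim$truth
#' @export
simulate_claims <- function(config = sim_config(),
                            code_config = txtrace::code_config()) {
  stopifnot(inherits(config, "sim_config"))
  cc <- code_config
  n <- config$n_patients
  dpy <- cc$days_per_year
  study_end <- as.Date(config$study_end)
  period_start <- as.Date(paste0(config$index_period[1], "-01-01"))
  # keep at least one day of follow-up after the index transplantation
  period_end <- min(as.Date(paste0(config$index_period[2], "-12-31")),
                    study_end - 1L)
  period_days <- as.integer(period_end - period_start)

  class_atc <- atc_for_classes(cc)
  other_atc <- "C09AA05"  # unmapped code used for database-presence claims
  # margin inside which a graft failure is indistinguishable from censoring
  loss_margin <- cc$treatment_gap_days + 2 * cc$coverage_days
  bela_min_days <- max(cc$cni_free_window[2],
                       2 * config$delivery_interval_days + 2)

  acc <- list(pat = list(), stay = list(), del = list(), dia = list(),
              truth = list(), tl = list())

  for (i in seq_len(n)) {
    set.seed(substream_seed(config$seed, i))
    pid <- sprintf("P%06d", i)

    index_date <- period_start + sample.int(period_days + 1L, 1L) - 1L
    age_class <- sample_one(names(config$age_class_weights),
                            prob = config$age_class_weights)
    underage <- runif(1) < config$underage_fraction
    bounds <- age_class_bounds[[age_class]]
    age <- if (underage) sample.int(8L, 1L) + 9L else
      sample.int(bounds[2] - bounds[1] + 1L, 1L) + bounds[1] - 1L
    birth_date <- index_date - as.integer(ceiling(age * dpy)) - sample.int(300L, 1L) + 1L
    sex <- if (runif(1) < config$missing_sex_fraction) "missing" else
      if (runif(1) < config$sex_split) "male" else "female"
    absent_prior <- runif(1) < config$absent_prior_fraction

    censor_day <- min(as.integer(study_end - index_date),
                      as.integer(floor(config$admin_censor_years * dpy)))
    censor_day <- max(censor_day, 1L)

    ld <- if (length(config$lambda_death) == 6)
      config$lambda_death[[match(age_class, names(config$age_class_weights))]]
    else config$lambda_death
    ev <- sample_event_times(1, config$lambda_graft, ld, censor_day / dpy)
    event <- ev$event
    event_day <- if (event == "censored") censor_day else
      max(1L, as.integer(round(ev$time * dpy)))
    if (event_day >= censor_day) {
      event_day <- censor_day
      if (event != "death") event <- "censored"
    }
    # a graft loss the 3-month-gap proxy cannot observe is emitted as censoring
    if (event == "graft_loss" && censor_day - event_day <= loss_margin) {
      event <- "censored"
      event_day <- censor_day
    }
    obs_end <- event_day  # last day of drug exposure (exclusive bound below)

    # --- regimen timeline ---------------------------------------------------
    long_enough <- obs_end >= bela_min_days
    if (runif(1) < config$belatacept_fraction && long_enough) {
      regimen <- "belatacept+mycophenolic_acid+corticosteroid"
    } else {
      regimen <- sample_one(names(config$regimen_mix), prob = config$regimen_mix)
    }
    seg_start <- 0L
    segments <- list()
    repeat {
      gap <- rexp(1, max(config$switch_rate, 1e-12)) * dpy
      switch_day <- seg_start + as.integer(ceiling(max(gap, config$min_switch_gap_days)))
      if (config$switch_rate <= 0 || switch_day >= obs_end - 1L) {
        segments[[length(segments) + 1L]] <- list(regimen, seg_start, obs_end)
        break
      }
      segments[[length(segments) + 1L]] <- list(regimen, seg_start, switch_day)
      cand <- relay_candidates(split_classes(regimen)[[1]], names(config$regimen_mix))
      if (obs_end - switch_day >= bela_min_days) {
        cand <- c(cand, "belatacept+mycophenolic_acid+corticosteroid")
      }
      cand <- setdiff(cand, regimen)
      regimen <- sample_one(cand)
      seg_start <- switch_day
    }

    # --- claims -------------------------------------------------------------
    stay_adm <- index_date
    stay_dis <- index_date + 10L
    stay_proc <- sample_one(cc$transplant_procedure_codes)
    stay_pdx <- ""
    stay_adx <- ""
    stay_chemo <- FALSE

    del_day <- integer(); del_atc <- character()
    dia_day <- integer()

    if (!absent_prior) {
      del_day <- c(del_day, -180L); del_atc <- c(del_atc, other_atc)
      if (runif(1) >= config$preemptive_fraction) {
        pre_dia <- seq(-360L, -15L, by = config$dialysis_interval_days)
        dia_day <- c(dia_day, pre_dia)
      }
      if (runif(1) < config$hypertension_prevalence) {
        stay_adm <- c(stay_adm, index_date - 200L)
        stay_dis <- c(stay_dis, index_date - 198L)
        stay_proc <- c(stay_proc, "")
        stay_pdx <- c(stay_pdx, cc$comorbidity_codelists$hypertension[1])
        stay_adx <- c(stay_adx, "")
        stay_chemo <- c(stay_chemo, FALSE)
      }
    }

    for (seg in segments) {
      cls <- split_classes(seg[[1]])[[1]]
      s <- seg[[2]]; e <- seg[[3]]
      if (e <= s) next
      sched <- seq(s, e - 1L, by = config$delivery_interval_days)
      for (cl in cls) {
        if (cl == "belatacept") {
          stay_adm <- c(stay_adm, index_date + sched)
          stay_dis <- c(stay_dis, index_date + sched)
          stay_proc <- c(stay_proc, rep("", length(sched)))
          stay_pdx <- c(stay_pdx, rep("", length(sched)))
          stay_adx <- c(stay_adx, rep(cc$transplant_diagnosis_codes[1], length(sched)))
          stay_chemo <- c(stay_chemo, rep(TRUE, length(sched)))
        } else {
          keep <- runif(length(sched)) >= config$missed_delivery_prob
          days <- sched[keep]
          if (config$delivery_delay_max_days > 0 && length(days) > 0) {
            days <- days + sample.int(config$delivery_delay_max_days + 1L,
                                      length(days), replace = TRUE) - 1L
          }
          del_day <- c(del_day, days)
          del_atc <- c(del_atc, rep(class_atc[[cl]], length(days)))
        }
      }
    }

    if (event == "graft_loss") {
      post_dia <- seq(event_day, censor_day, by = config$dialysis_interval_days)
      dia_day <- c(dia_day, post_dia)
    }
    if (config$extra_chemo_stay_rate > 0) {
      n_extra <- stats::rpois(1, config$extra_chemo_stay_rate)
      if (n_extra > 0) {
        d <- sample.int(max(obs_end, 1L), n_extra, replace = TRUE)
        stay_adm <- c(stay_adm, index_date + d)
        stay_dis <- c(stay_dis, index_date + d)
        stay_proc <- c(stay_proc, rep("", n_extra))
        stay_pdx <- c(stay_pdx, rep("C349", n_extra))  # tumoral context
        stay_adx <- c(stay_adx, rep("", n_extra))
        stay_chemo <- c(stay_chemo, rep(TRUE, n_extra))
      }
    }

    death_date <- if (event == "death") index_date + event_day else as.Date(NA)

    acc$pat[[i]] <- list(pid, as.integer(birth_date), sex, as.integer(death_date))
    acc$stay[[i]] <- list(rep(pid, length(stay_adm)), as.integer(stay_adm),
                          as.integer(stay_dis), stay_proc, stay_pdx, stay_adx,
                          stay_chemo)
    acc$del[[i]] <- list(rep(pid, length(del_day)),
                         as.integer(index_date) + del_day, del_atc)
    acc$dia[[i]] <- list(rep(pid, length(dia_day)),
                         as.integer(index_date) + dia_day)
    acc$truth[[i]] <- list(pid, as.integer(index_date), age_class, age, sex,
                           !absent_prior && !underage && sex != "missing",
                           segments[[1]][[1]],
                           any(grepl("belatacept", vapply(segments, `[[`, "", 1))),
                           event, event_day / dpy, censor_day / dpy,
                           length(segments) - 1L)
    acc$tl[[i]] <- list(rep(pid, length(segments)),
                        vapply(segments, `[[`, "", 1),
                        vapply(segments, function(s) as.integer(s[[2]]), 1L),
                        vapply(segments, function(s) as.integer(s[[3]]), 1L))
  }

  pull <- function(lst, k) unlist(lapply(lst, `[[`, k))
  as_date <- function(x) as.Date(x %||% integer(), origin = "1970-01-01")

  patients <- tibble::tibble(
    patient_id = pull(acc$pat, 1) %||% character(),
    birth_date = as_date(pull(acc$pat, 2)),
    sex = pull(acc$pat, 3) %||% character(),
    death_date = as_date(pull(acc$pat, 4)))
  stays <- tibble::tibble(
    patient_id = pull(acc$stay, 1) %||% character(),
    admission_date = as_date(pull(acc$stay, 2)),
    discharge_date = as_date(pull(acc$stay, 3)),
    procedure_codes = pull(acc$stay, 4) %||% character(),
    principal_diagnosis = pull(acc$stay, 5) %||% character(),
    associated_diagnoses = pull(acc$stay, 6) %||% character(),
    is_chemo_delivery = pull(acc$stay, 7) %||% logical())
  deliveries <- tibble::tibble(
    patient_id = pull(acc$del, 1) %||% character(),
    delivery_date = as_date(pull(acc$del, 2)),
    atc_code = pull(acc$del, 3) %||% character(),
    presentation_id = rep("", length(pull(acc$del, 3) %||% character())))
  dialysis <- tibble::tibble(
    patient_id = pull(acc$dia, 1) %||% character(),
    session_date = as_date(pull(acc$dia, 2)))

  truth <- tibble::tibble(
    patient_id = pull(acc$truth, 1) %||% character(),
    index_date = as_date(pull(acc$truth, 2)),
    age_class = pull(acc$truth, 3) %||% character(),
    age_at_index = pull(acc$truth, 4) %||% integer(),
    sex = pull(acc$truth, 5) %||% character(),
    eligible = pull(acc$truth, 6) %||% logical(),
    initial_regimen = pull(acc$truth, 7) %||% character(),
    belatacept_ever = pull(acc$truth, 8) %||% logical(),
    event = pull(acc$truth, 9) %||% character(),
    event_years = pull(acc$truth, 10) %||% numeric(),
    censor_years = pull(acc$truth, 11) %||% numeric(),
    n_switches = pull(acc$truth, 12) %||% integer())
  truth_timeline <- tibble::tibble(
    patient_id = pull(acc$tl, 1) %||% character(),
    regimen = pull(acc$tl, 2) %||% character(),
    start_day = pull(acc$tl, 3) %||% integer(),
    end_day = pull(acc$tl, 4) %||% integer())

  bundle <- claims_bundle(patients, stays, deliveries, dialysis, cc)
  list(bundle = bundle, truth = truth, truth_timeline = truth_timeline)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One representative ATC code per molecule class, inverted from the config map.
atc_for_classes <- function(code_config) {
  m <- code_config$drug_class_map
  out <- lapply(setdiff(drug_classes(), c("other", "belatacept")), function(cl) {
    hit <- names(m)[m == cl]
    if (length(hit) == 0) stop("drug_class_map has no ATC code for class ", cl)
    hit[1]
  })
  names(out) <- setdiff(drug_classes(), c("other", "belatacept"))
  out
}

#' Perturb a synthetic bundle without touching its ground truth
#'
#' Robustness harness: drops pharmacy deliveries at random, inserts
#' non-qualifying chemotherapy stays (tumoral context, no transplant
#' diagnosis), and delays deliveries, so that phenotype recovery can be
#' measured against an unchanged truth.
#'
#' @param bundle A `claims_bundle` produced by [simulate_claims()].
#' @param drop_prob Per-delivery drop probability.
#' @param extra_chemo_rate Expected number of inserted chemo stays per patient.
#' @param delay_max_days Maximum uniform delay added to each delivery.
#' @param seed Integer seed.
#' @return A perturbed `claims_bundle`.
#' @export
corrupt_bundle <- function(bundle, drop_prob = 0, extra_chemo_rate = 0,
                           delay_max_days = 0, seed = 1L) {
  set.seed(seed)
  del <- bundle$deliveries
  if (drop_prob > 0 && nrow(del) > 0) {
    del <- del[runif(nrow(del)) >= drop_prob, , drop = FALSE]
  }
  if (delay_max_days > 0 && nrow(del) > 0) {
    del$delivery_date <- del$delivery_date +
      sample.int(delay_max_days + 1L, nrow(del), replace = TRUE) - 1L
  }
  stays <- bundle$stays
  if (extra_chemo_rate > 0 && nrow(bundle$patients) > 0) {
    n_extra <- stats::rpois(nrow(bundle$patients), extra_chemo_rate)
    idx <- rep(seq_len(nrow(bundle$patients)), n_extra)
    if (length(idx) > 0) {
      dates <- bundle$patients$birth_date[idx] +
        sample.int(20000L, length(idx), replace = TRUE)
      stays <- dplyr::bind_rows(stays, tibble::tibble(
        patient_id = bundle$patients$patient_id[idx],
        admission_date = dates, discharge_date = dates,
        procedure_codes = "", principal_diagnosis = "C349",
        associated_diagnoses = "", is_chemo_delivery = TRUE))
    }
  }
  claims_bundle(bundle$patients, stays, del, bundle$dialysis, bundle$code_config)
}
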