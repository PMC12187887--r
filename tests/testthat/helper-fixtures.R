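# Fixture builders and independent brute-force oracles shared by the suite.

d0 <- as.Date("2015-01-01")

mk_patients <- function(ids, birth = as.Date("1970-06-15"), sex = "male",
                        death = as.Date(NA)) {
  tibble::tibble(patient_id = ids, birth_date = rep_len(birth, length(ids)),
                 sex = rep_len(sex, length(ids)),
                 death_date = rep_len(death, length(ids)))
}

mk_stay <- function(id, admission, discharge = admission, proc = "",
                    pdx = "", adx = "", chemo = FALSE) {
  tibble::tibble(patient_id = id, admission_date = as.Date(admission),
                 discharge_date = as.Date(discharge), procedure_codes = proc,
                 principal_diagnosis = pdx, associated_diagnoses = adx,
                 is_chemo_delivery = chemo)
}

mk_del <- function(id, dates, atc) {
  tibble::tibble(patient_id = id, delivery_date = as.Date(dates),
                 atc_code = atc, presentation_id = "")
}

mk_dial <- function(id, dates) {
  tibble::tibble(patient_id = id, session_date = as.Date(dates))
}

mk_bundle <- function(patients = mk_patients("a"),
                      stays = empty_tbl("stays"),
                      deliveries = empty_tbl("deliveries"),
                      dialysis = empty_tbl("dialysis"),
                      config = code_config()) {
  claims_bundle(patients, stays, deliveries, dialysis, config)
}

empty_tbl <- function(which) {
  switch(which,
    stays = mk_stay(character(), as.Date(character())),
    deliveries = mk_del(character(), as.Date(character()), character()),
    dialysis = mk_dial(character(), as.Date(character())))
}

# A randomized but valid bundle, for round-trip and validation properties.
random_bundle <- function(n = 20, seed = 1) {
  set.seed(seed)
  cfg <- code_config()
  ids <- sprintf("pt%03d", seq_len(n))
  atcs <- c(names(cfg$drug_class_map), "X99XX99")
  patients <- tibble::tibble(
    patient_id = ids,
    birth_date = d0 - sample(7000:25000, n, replace = TRUE),
    sex = sample(c("male", "female", "missing"), n, replace = TRUE),
    death_date = dplyr::if_else(runif(n) < 0.2, d0 + sample(0:2000, n, TRUE),
                                as.Date(NA)))
  stay_id <- sample(ids, n * 2, replace = TRUE)
  adm <- d0 + sample(-500:2000, n * 2, replace = TRUE)
  stays <- tibble::tibble(
    patient_id = stay_id, admission_date = adm,
    discharge_date = adm + sample(0:20, n * 2, replace = TRUE),
    procedure_codes = sample(c("", "JAE003", "HNEA002", "AAAA01"), n * 2, TRUE),
    principal_diagnosis = sample(c("", "I10", "Z940"), n * 2, TRUE),
    associated_diagnoses = sample(c("", "E66", "Z940|T861"), n * 2, TRUE),
    is_chemo_delivery = runif(n * 2) < 0.3)
  deliveries <- tibble::tibble(
    patient_id = sample(ids, n * 5, replace = TRUE),
    delivery_date = d0 + sample(-400:2000, n * 5, replace = TRUE),
    atc_code = sample(atcs, n * 5, replace = TRUE),
    presentation_id = sample(c("", "123", "987"), n * 5, TRUE))
  dialysis <- tibble::tibble(
    patient_id = sample(ids, n * 3, replace = TRUE),
    session_date = d0 + sample(-400:2000, n * 3, replace = TRUE))
  claims_bundle(patients, stays, deliveries, dialysis, cfg)
}

# ---- independent oracles ---------------------------------------------------

# product-limit estimate by explicit risk-set recomputation at each time
km_oracle <- function(times, events) {
  ts <- sort(unique(times))
  s <- 1
  est <- numeric(length(ts))
  for (i in seq_along(ts)) {
    n_risk <- sum(times >= ts[i])
    d <- sum(times == ts[i] & events)
    s <- s * (1 - d / n_risk)
    est[i] <- s
  }
  tibble::tibble(time = ts, estimate = est)
}

# Aalen-Johansen by explicit step accumulation
aj_oracle <- function(times, codes) {
  ts <- sort(unique(times))
  s <- 1; f1 <- 0; f2 <- 0
  out <- vector("list", length(ts))
  for (i in seq_along(ts)) {
    n_risk <- sum(times >= ts[i])
    d1 <- sum(times == ts[i] & codes == 1)
    d2 <- sum(times == ts[i] & codes == 2)
    f1 <- f1 + s * d1 / n_risk
    f2 <- f2 + s * d2 / n_risk
    s <- s * (1 - (d1 + d2) / n_risk)
    out[[i]] <- c(ts[i], s, f1, f2)
  }
  res <- do.call(rbind, out)
  tibble::tibble(time = res[, 1], surv = res[, 2], cif1 = res[, 3],
                 cif2 = res[, 4])
}

# closed-form cumulative incidence under constant cause-specific hazards
cif_closed_form <- function(t, lambda1, lambda2) {
  tot <- lambda1 + lambda2
  lambda1 / tot * (1 - exp(-t * tot))
}

# day-by-day coverage bitmap for one class (delivery day offsets)
coverage_bitmap <- function(days, coverage, horizon) {
  bit <- rep(FALSE, horizon)
  for (d in days) {
    lo <- d + 1          # day offsets are 0-based; bitmap index 1-based
    hi <- min(d + coverage, horizon)
    if (hi >= lo) bit[lo:hi] <- TRUE
  }
  bit
}

# exhaustive enumeration of the belatacept algorithm on raw event streams:
# stay_days = qualifying-stay day offsets; del = data.frame(day, group)
belatacept_oracle <- function(stay_days, del, cfg = code_config()) {
  m <- cfg$belatacept_min_stays
  w <- cfg$belatacept_window_days
  stay_days <- sort(unique(stay_days))
  if (length(stay_days) < m) return(list(positive = FALSE, hosp = NA))
  sets <- utils::combn(stay_days, m)
  qualifying <- sets[, apply(sets, 2, function(s) max(s) - min(s) <= w),
                     drop = FALSE]
  if (ncol(qualifying) == 0) return(list(positive = FALSE, hosp = NA))
  hosp <- min(qualifying[1, ])
  companion <- any(del$group %in% c("mTORi", "antimetabolite") &
                     del$day >= hosp & del$day <= hosp + w)
  cni_free <- !any(del$group == "CNI" &
                     del$day >= hosp + cfg$cni_free_window[1] &
                     del$day < hosp + cfg$cni_free_window[2])
  list(positive = companion && cni_free, hosp = hosp,
       companion = companion, cni_free = cni_free)
}

# tolerance-free set comparison of +-joined class keys
key_of <- function(x) paste(sort(x, method = "radix"), collapse = "+")

truth_group_key <- function(regimen) {
  vapply(strsplit(regimen, "+", fixed = TRUE),
         function(cl) key_of(unique(roll_up_class(cl))), "")
}
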