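#' Build per-patient drug-class coverage timelines
#'
#' Each pharmacy delivery grants `coverage_days` of exposure to its molecule
#' class, as the half-open interval `[day, day + coverage_days)` in days from
#' the patient's index date. Per class, coverage windows separated by at most
#' `merge_gap_days` are merged into one episode; larger gaps split episodes.
#' Deliveries classified as `other` (non-immunosuppressive) are ignored.
#'
#' @param deliveries Delivery tibble, classified by [classify_deliveries()]
#'   (classification is applied here if the `drug_class` column is absent).
#' @param index_events Tibble with `patient_id` and `index_date` columns.
#' @param code_config A [code_config()].
#' @return Tibble with columns `patient_id`, `drug_class`, `class_group`,
#'   `start_day`, `end_day`, `n_deliveries` — one row per coverage episode,
#'   disjoint and sorted within patient and class.
#' @examples
#' cfg <- code_config()
#' idx <- tibble::tibble(patient_id = "a", index_date = as.Date("2015-01-01"))
#' del <- tibble::tibble(patient_id = "a",
#'                       delivery_date = as.Date("2015-01-01") + c(0, 30, 60, 200),
#'                       atc_code = "L04AD02", presentation_id = "")
#' build_timeline(del, idx, cfg)  # episodes [0,90) and [200,230)
#' @export
build_timeline <- function(deliveries, index_events, code_config = txtrace::code_config()) {
  if (!"drug_class" %in% names(deliveries)) {
    deliveries <- classify_deliveries(deliveries, code_config)
  }
  cov <- code_config$coverage_days
  gap <- code_config$merge_gap_days
  empty <- tibble::tibble(patient_id = character(), drug_class = character(),
                          class_group = character(), start_day = integer(),
                          end_day = numeric(), n_deliveries = integer())
  del <- deliveries |>
    dplyr::filter(.data$drug_class != "other") |>
    dplyr::inner_join(dplyr::select(index_events, "patient_id", "index_date"),
                      by = "patient_id", relationship = "many-to-one") |>
    dplyr::mutate(day = as.integer(.data$delivery_date - .data$index_date)) |>
    dplyr::distinct(.data$patient_id, .data$drug_class, .data$class_group, .data$day)
  if (nrow(del) == 0) return(empty)
  del |>
    dplyr::arrange(.data$patient_id, .data$drug_class, .data$day) |>
    dplyr::group_by(.data$patient_id, .data$drug_class, .data$class_group) |>
    dplyr::mutate(new_episode = is.na(dplyr::lag(.data$day)) |
                    .data$day - dplyr::lag(.data$day) > cov + gap,
                  episode = cumsum(.data$new_episode)) |>
    dplyr::group_by(.data$episode, .add = TRUE) |>
    dplyr::summarise(start_day = min(.data$day),
                     end_day = max(.data$day) + cov,
                     n_deliveries = dplyr::n(), .groups = "drop") |>
    dplyr::select("patient_id", "drug_class", "class_group",
                  "start_day", "end_day", "n_deliveries") |>
    dplyr::arrange(.data$patient_id, .data$drug_class, .data$start_day)
}

backbone_key <- function(groups) {
  g <- sort_c(unique(setdiff(groups, "corticosteroid")))
  paste(g, collapse = "+")
}

regimen_recognized <- function(groups, recognized_regimens) {
  backbone <- sort_c(unique(setdiff(groups, "corticosteroid")))
  if (length(backbone) <= 1) return(TRUE)
  any(vapply(recognized_regimens,
             function(r) identical(sort_c(r), backbone), logical(1)))
}

#' Partition follow-up into regimen periods and label combinations
#'
#' Sweeps each patient's coverage episodes to obtain maximal periods of
#' constant covered-class set. A period with more than one molecule class
#' lasting under 30 days is transition slack: it is absorbed into the
#' adjacent (preferentially preceding) period. A surviving multi-drug period
#' is a recognised combination only when its non-steroid class-group set is
#' listed in `recognized_regimens`; single-backbone periods are always
#' recognised and corticosteroids never affect recognition.
#'
#' @param timeline Output of [build_timeline()].
#' @param code_config A [code_config()].
#' @return Tibble with columns `patient_id`, `start_day`, `end_day`,
#'   `classes` (sorted `+`-joined molecule classes), `groups` (sorted
#'   `+`-joined class groups), `backbone` (groups without corticosteroids),
#'   `recognized`.
#' @export
detect_combinations <- function(timeline, code_config = txtrace::code_config()) {
  min_dur <- 30L
  empty <- tibble::tibble(patient_id = character(), start_day = integer(),
                          end_day = integer(), classes = character(),
                          groups = character(), backbone = character(),
                          recognized = logical())
  if (nrow(timeline) == 0) return(empty)
  res <- timeline |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::group_map(function(tl, key) {
      per <- sweep_periods(tl, min_dur)
      if (nrow(per) == 0) return(NULL)
      per$patient_id <- key$patient_id
      per
    }) |>
    dplyr::bind_rows()
  if (nrow(res) == 0) return(empty)
  res |>
    dplyr::mutate(
      backbone = vapply(split_classes(.data$groups), backbone_key, ""),
      recognized = vapply(split_classes(.data$groups), regimen_recognized, TRUE,
                          recognized_regimens = code_config$recognized_regimens)) |>
    dplyr::select("patient_id", "start_day", "end_day", "classes", "groups",
                  "backbone", "recognized") |>
    dplyr::arrange(.data$patient_id, .data$start_day)
}

# Boundary sweep for one patient's episodes, with <30-day multi-class
# transition slack absorbed into the neighbouring period.
sweep_periods <- function(tl, min_dur) {
  pts <- sort(unique(c(tl$start_day, tl$end_day)))
  if (length(pts) < 2) return(tibble::tibble())
  seg <- tibble::tibble(start_day = pts[-length(pts)], end_day = pts[-1])
  seg$classes <- vapply(seq_len(nrow(seg)), function(i) {
    active <- tl$drug_class[tl$start_day <= seg$start_day[i] &
                              tl$end_day >= seg$end_day[i]]
    paste(sort_c(unique(active)), collapse = "+")
  }, "")
  seg$groups <- vapply(seq_len(nrow(seg)), function(i) {
    active <- tl$class_group[tl$start_day <= seg$start_day[i] &
                               tl$end_day >= seg$end_day[i]]
    paste(sort_c(unique(active)), collapse = "+")
  }, "")
  seg <- seg[seg$classes != "", , drop = FALSE]
  if (nrow(seg) == 0) return(tibble::tibble())
  seg <- merge_equal_adjacent(seg)
  repeat {
    dur <- seg$end_day - seg$start_day
    multi <- lengths(split_classes(seg$classes)) > 1
    short <- which(dur < min_dur & multi)
    short <- Filter(function(i) {
      (i > 1 && seg$end_day[i - 1] == seg$start_day[i]) ||
        (i < nrow(seg) && seg$start_day[i + 1] == seg$end_day[i])
    }, short)
    if (length(short) == 0) break
    i <- short[1]
    if (i > 1 && seg$end_day[i - 1] == seg$start_day[i]) {
      seg$end_day[i - 1] <- seg$end_day[i]
    } else {
      seg$start_day[i + 1] <- seg$start_day[i]
    }
    seg <- seg[-i, , drop = FALSE]
    seg <- merge_equal_adjacent(seg)
  }
  seg
}

merge_equal_adjacent <- function(seg) {
  if (nrow(seg) < 2) return(seg)
  same <- c(FALSE, seg$classes[-1] == seg$classes[-nrow(seg)] &
              seg$start_day[-1] == seg$end_day[-nrow(seg)])
  grp <- cumsum(!same)
  out <- seg |>
    dplyr::mutate(grp = grp) |>
    dplyr::group_by(.data$grp) |>
    dplyr::summarise(start_day = min(.data$start_day),
                     end_day = max(.data$end_day),
                     classes = dplyr::first(.data$classes),
                     groups = dplyr::first(.data$groups), .groups = "drop") |>
    dplyr::select(-"grp")
  out
}

#' Identify belatacept-treated patients from infusion-stay patterns
#'
#' Belatacept is infused in hospital and is invisible in community-pharmacy
#' claims (before retrocession), so exposure is inferred from an algorithm
#' with three clauses: (1) at least `belatacept_min_stays` hospitalizations
#' for chemotherapy delivery for a non-tumoral disease, carrying a
#' kidney-transplant diagnosis code, with admission dates spanning at most
#' `belatacept_window_days`; the index hospitalization is the earliest stay
#' of the earliest qualifying window; (2) at least one mTOR-inhibitor or
#' antimetabolite delivery within `belatacept_window_days` (inclusive) of
#' the index hospitalization; (3) no CNI delivery during the fourth month
#' after the index hospitalization (days 91-120). A delivery whose ATC code
#' maps directly to belatacept (retrocession) short-circuits to a positive
#' call.
#'
#' @param stays Stay tibble (with `is_chemo_delivery` and diagnosis columns).
#' @param deliveries Classified delivery tibble.
#' @param index_events Tibble with `patient_id`, `index_date`.
#' @param code_config A [code_config()].
#' @return Tibble with one row per patient in `index_events`: `positive`,
#'   `source` (`"algorithm"`, `"direct_retrocession"` or `"none"`),
#'   `index_hosp_day`, and the three clause flags (`NA` when clause 1 fails
#'   and no window anchors the later clauses).
#' @export
detect_belatacept <- function(stays, deliveries, index_events,
                              code_config = txtrace::code_config()) {
  cc <- code_config
  if (!"drug_class" %in% names(deliveries)) {
    deliveries <- classify_deliveries(deliveries, cc)
  }
  idx <- dplyr::select(index_events, "patient_id", "index_date")
  qual <- stays |>
    dplyr::inner_join(idx, by = "patient_id", relationship = "many-to-one") |>
    dplyr::filter(.data$is_chemo_delivery,
                  codes_match(paste(.data$principal_diagnosis,
                                    .data$associated_diagnoses, sep = "|"),
                              cc$transplant_diagnosis_codes)) |>
    dplyr::mutate(day = as.integer(.data$admission_date - .data$index_date))
  del <- deliveries |>
    dplyr::inner_join(idx, by = "patient_id", relationship = "many-to-one") |>
    dplyr::mutate(day = as.integer(.data$delivery_date - .data$index_date))
  direct <- unique(del$patient_id[del$drug_class == "belatacept"])

  qual_by <- split(qual$day, qual$patient_id)
  cand <- names(qual_by)
  del_cand <- del[del$patient_id %in% cand,
                  c("patient_id", "class_group", "day")]
  del_by <- split(seq_len(nrow(del_cand)), del_cand$patient_id)
  cand_calls <- lapply(cand, function(pid) {
    days <- sort(unique(qual_by[[pid]]))
    hosp <- belatacept_index_hosp(days, cc$belatacept_min_stays,
                                  cc$belatacept_window_days)
    if (is.na(hosp)) {
      return(list(pid, FALSE, NA, NA, NA_integer_))
    }
    d <- del_cand[del_by[[pid]] %||% integer(), , drop = FALSE]
    companion <- any(d$class_group %in% c("mTORi", "antimetabolite") &
                       d$day >= hosp & d$day <= hosp + cc$belatacept_window_days)
    cni_free <- !any(d$class_group == "CNI" &
                       d$day >= hosp + cc$cni_free_window[1] &
                       d$day < hosp + cc$cni_free_window[2])
    list(pid, TRUE, companion, cni_free, hosp)
  })
  others <- setdiff(index_events$patient_id, cand)
  calls <- dplyr::bind_rows(
    tibble::tibble(
      patient_id = vapply(cand_calls, `[[`, "", 1),
      three_stays = vapply(cand_calls, `[[`, TRUE, 2),
      companion = vapply(cand_calls, `[[`, TRUE, 3),
      cni_free = vapply(cand_calls, `[[`, TRUE, 4),
      index_hosp_day = vapply(cand_calls, `[[`, 1L, 5)),
    tibble::tibble(patient_id = others, three_stays = FALSE, companion = NA,
                   cni_free = NA, index_hosp_day = NA_integer_))
  calls |>
    dplyr::mutate(
      algorithm_positive = .data$three_stays &
        dplyr::coalesce(.data$companion, FALSE) &
        dplyr::coalesce(.data$cni_free, FALSE),
      positive = .data$algorithm_positive | .data$patient_id %in% direct,
      source = dplyr::case_when(
        .data$patient_id %in% direct ~ "direct_retrocession",
        .data$algorithm_positive ~ "algorithm",
        TRUE ~ "none")) |>
    dplyr::select("patient_id", "positive", "source", "index_hosp_day",
                  "three_stays", "companion", "cni_free")
}

#' Convert infusion stays of belatacept-positive patients into coverage
#' episodes
#'
#' Belatacept exposure leaves no community-pharmacy trace, so the qualifying
#' infusion stays of algorithm-positive patients are converted into
#' timeline-shaped coverage episodes (same coverage and merge rules as
#' deliveries). Binding these rows to the delivery timeline lets the
#' combination, switch and graft-loss rules see belatacept like any other
#' class.
#'
#' @param stays Stay tibble.
#' @param belatacept_calls Output of [detect_belatacept()].
#' @param index_events Tibble with `patient_id`, `index_date`.
#' @param code_config A [code_config()].
#' @return Tibble in [build_timeline()] layout with `drug_class`
#'   `"belatacept"`.
#' @export
belatacept_episodes <- function(stays, belatacept_calls, index_events,
                                code_config = txtrace::code_config()) {
  cc <- code_config
  pos <- belatacept_calls$patient_id[belatacept_calls$positive]
  inf <- stays |>
    dplyr::filter(.data$patient_id %in% pos, .data$is_chemo_delivery,
                  codes_match(paste(.data$principal_diagnosis,
                                    .data$associated_diagnoses, sep = "|"),
                              cc$transplant_diagnosis_codes)) |>
    dplyr::inner_join(dplyr::select(index_events, "patient_id", "index_date"),
                      by = "patient_id", relationship = "many-to-one") |>
    dplyr::transmute(.data$patient_id,
                     delivery_date = .data$admission_date,
                     atc_code = "",
                     drug_class = "belatacept", class_group = "belatacept")
  build_timeline(inf, index_events, cc)
}

# Earliest stay of the earliest window of >= m qualifying stays spanning <= w
# days; NA when no window qualifies.
belatacept_index_hosp <- function(days, m, w) {
  if (length(days) < m) return(NA_integer_)
  for (i in seq_len(length(days) - m + 1)) {
    if (days[i + m - 1] - days[i] <= w) return(days[i])
  }
  NA_integer_
}

#' Detect treatment switches and add-ons
#'
#' A relay event fires whenever a non-steroid drug class starts a new
#' coverage episode after the initial-regimen window. The prior regimen is
#' the set of non-steroid classes covered on the day before the arrival; the
#' event is an `add_on` when every prior class keeps at least 30 days of
#' coverage alongside the new class (inclusive: exactly 30 residual days
#' counts as add-on), and a `switch` otherwise, dated at the relay class's
#' first delivery. Arrivals with no prior coverage (restart after a full
#' treatment gap) are not relay events.
#'
#' @param timeline Output of [build_timeline()].
#' @param code_config A [code_config()].
#' @return Tibble with columns `patient_id`, `day`, `from_classes`,
#'   `to_classes` (sorted `+`-joined), `kind` (`"switch"` or `"add_on"`),
#'   and `order` (1 for the first relay, 2 for the next, ...).
#' @export
detect_switches <- function(timeline, code_config = txtrace::code_config()) {
  residual <- 30L
  win <- code_config$initial_window_days
  empty <- tibble::tibble(patient_id = character(), day = integer(),
                          from_classes = character(), to_classes = character(),
                          kind = character(), order = integer())
  tl <- dplyr::filter(timeline, .data$drug_class != "corticosteroid")
  arrivals <- tl |>
    dplyr::filter(.data$start_day > win) |>
    dplyr::distinct(.data$patient_id, day = .data$start_day, .data$drug_class)
  if (nrow(arrivals) == 0) return(empty)
  events <- arrivals |>
    dplyr::distinct(.data$patient_id, .data$day) |>
    dplyr::inner_join(tl, by = "patient_id", relationship = "many-to-many") |>
    dplyr::group_by(.data$patient_id, .data$day) |>
    dplyr::summarise(
      from = list(sort_c(unique(.data$drug_class[.data$start_day <= .data$day - 1L &
                                                 .data$end_day > .data$day - 1L]))),
      continuing = list(sort_c(unique(
        .data$drug_class[.data$start_day <= .data$day &
                           .data$end_day >= .data$day + residual]))),
      .groups = "drop")
  new_cls <- arrivals |>
    dplyr::group_by(.data$patient_id, .data$day) |>
    dplyr::summarise(new = list(sort_c(unique(.data$drug_class))), .groups = "drop")
  events |>
    dplyr::inner_join(new_cls, by = c("patient_id", "day")) |>
    dplyr::filter(lengths(.data$from) > 0) |>
    dplyr::mutate(
      to = purrr::map2(.data$new, .data$continuing, ~ sort_c(union(.x, .y))),
      kind = ifelse(purrr::map2_lgl(.data$from, .data$continuing,
                                    ~ all(.x %in% .y)),
                    "add_on", "switch"),
      from_classes = purrr::map_chr(.data$from, paste, collapse = "+"),
      to_classes = purrr::map_chr(.data$to, paste, collapse = "+")) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::arrange(.data$day, .by_group = TRUE) |>
    dplyr::mutate(order = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::select("patient_id", "day", "from_classes", "to_classes",
                  "kind", "order")
}

#' Determine the initial maintenance regimen
#'
#' The initial regimen is the set of class groups with any drug coverage
#' intersecting the initial window `[0, initial_window_days]` after index.
#' A positive belatacept call whose index hospitalization falls inside the
#' window contributes belatacept. Patients with neither yield an empty
#' regimen (no documented immunosuppressive treatment, e.g. early death
#' before any community delivery).
#'
#' @param timeline Output of [build_timeline()].
#' @param belatacept_calls Output of [detect_belatacept()].
#' @param index_events Tibble with `patient_id` (denominator population).
#' @param code_config A [code_config()].
#' @return Tibble with `patient_id`, `initial_groups` (sorted `+`-joined
#'   class groups, `""` when none).
#' @export
initial_regimen <- function(timeline, belatacept_calls, index_events,
                            code_config = txtrace::code_config()) {
  win <- code_config$initial_window_days
  from_del <- timeline |>
    dplyr::filter(.data$start_day <= win, .data$end_day > 0) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(groups = list(unique(.data$class_group)), .groups = "drop")
  bela <- belatacept_calls |>
    dplyr::filter(.data$positive, !is.na(.data$index_hosp_day),
                  .data$index_hosp_day <= win) |>
    dplyr::pull("patient_id")
  index_events |>
    dplyr::distinct(.data$patient_id) |>
    dplyr::left_join(from_del, by = "patient_id") |>
    dplyr::mutate(
      groups = purrr::map2(.data$groups, .data$patient_id %in% bela, function(g, b) {
        union(g %||% character(), if (b) "belatacept" else character())
      }),
      initial_groups = purrr::map_chr(.data$groups, ~ paste(sort_c(.x), collapse = "+"))) |>
    dplyr::select("patient_id", "initial_groups")
}
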