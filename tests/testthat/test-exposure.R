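idx_a <- tibble::tibble(patient_id = "a", index_date = d0)

tl_of <- function(days, atc = "L04AD02", cfg = code_config()) {
  build_timeline(mk_del("a", d0 + days, atc), idx_a, cfg)
}

test_that("coverage windows merge when abutting and split across large gaps", {
  tl <- tl_of(c(0, 30, 60))
  expect_equal(nrow(tl), 1)
  expect_equal(c(tl$start_day, tl$end_day), c(0, 90))
  tl2 <- tl_of(c(0, 200))
  expect_equal(tl2$start_day, c(0, 200))
  expect_equal(tl2$end_day, c(30, 230))
  # gap exactly at the merge limit still merges (61-day spacing, 30+31)
  tl3 <- tl_of(c(0, 61))
  expect_equal(nrow(tl3), 1)
  expect_equal(tl3$end_day, 91)
  tl4 <- tl_of(c(0, 62))
  expect_equal(nrow(tl4), 2)
})

test_that("timelines match a day-by-day coverage bitmap on random delivery sets", {
  cfg <- code_config()
  horizon <- 800L
  for (seed in 1:8) {
    set.seed(seed)
    days <- sort(sample(0:700, sample(1:25, 1)))
    tl <- tl_of(days, cfg = cfg)
    got <- coverage_bitmap(unlist(Map(seq, tl$start_day, tl$end_day - 1)),
                           1, horizon)
    # oracle: union of per-delivery windows, then close gaps <= merge_gap_days
    bit <- coverage_bitmap(days, cfg$coverage_days, horizon)
    runs <- rle(bit)
    pos <- cumsum(runs$lengths)
    for (r in which(!runs$values)) {
      if (r == 1 || r == length(runs$values)) next
      if (runs$lengths[r] <= cfg$merge_gap_days) {
        bit[(pos[r] - runs$lengths[r] + 1):pos[r]] <- TRUE
      }
    }
    expect_identical(got, bit, info = paste("seed", seed))
    # every delivery date lies inside exactly one interval of its class
    inside <- vapply(days, function(d) sum(tl$start_day <= d & d < tl$end_day), 1L)
    expect_true(all(inside == 1L))
  }
})

test_that("combinations need 30 days of overlap and a recognized backbone", {
  cfg <- code_config()
  del <- dplyr::bind_rows(
    mk_del("a", d0 + seq(0, 360, 30), "L04AD02"),     # tacrolimus all year
    mk_del("a", d0 + seq(0, 360, 30), "L04AA06"))     # mycophenolate all year
  per <- detect_combinations(build_timeline(del, idx_a, cfg), cfg)
  expect_equal(nrow(per), 1)
  expect_equal(per$backbone, "CNI+antimetabolite")
  expect_true(per$recognized)
  expect_equal(per$end_day - per$start_day, 390)

  # 25-day tail overlap is transition slack, not a combination
  del2 <- dplyr::bind_rows(
    mk_del("a", d0 + seq(0, 335, 30), "L04AD02"),
    mk_del("a", d0 + 340, "L04AA18"))
  per2 <- detect_combinations(build_timeline(del2, idx_a, cfg), cfg)
  expect_false(any(grepl("\\+", per2$backbone)))

  # unrecognized pairs keep their period but are flagged unrecognized
  cfg_strict <- code_config(recognized_regimens = list(c("CNI", "mTORi")))
  del3 <- dplyr::bind_rows(
    mk_del("a", d0 + seq(0, 180, 30), "L04AD02"),
    mk_del("a", d0 + seq(0, 180, 30), "L04AA06"))
  per3 <- detect_combinations(build_timeline(del3, idx_a, cfg_strict), cfg_strict)
  expect_true(any(per3$backbone == "CNI+antimetabolite" & !per3$recognized))
})

test_that("corticosteroid coverage never changes a combination's backbone or recognition", {
  cfg <- code_config()
  base <- dplyr::bind_rows(
    mk_del("a", d0 + seq(0, 360, 30), "L04AD02"),
    mk_del("a", d0 + seq(0, 360, 30), "L04AA06"))
  with_cs <- dplyr::bind_rows(base, mk_del("a", d0 + seq(0, 360, 30), "H02AB06"))
  p1 <- detect_combinations(build_timeline(base, idx_a, cfg), cfg)
  p2 <- detect_combinations(build_timeline(with_cs, idx_a, cfg), cfg)
  expect_equal(p1$backbone, p2$backbone)
  expect_equal(p1$recognized, p2$recognized)
})

test_that("regimen periods equal a per-day class-set scan on random timelines", {
  cfg <- code_config()
  classes <- c("L04AD02", "L04AA06", "L04AA18", "H02AB06")
  for (seed in 1:6) {
    set.seed(seed)
    del <- dplyr::bind_rows(lapply(sample(classes, sample(2:4, 1)), function(atc) {
      n <- sample(3:12, 1)
      mk_del("a", d0 + sort(sample(0:500, n)), atc)
    }))
    tl <- build_timeline(del, idx_a, cfg)
    per <- detect_combinations(tl, cfg)
    # oracle: run-length encode per-day class sets, then apply the 30-day
    # transition-slack rule post hoc
    horizon <- max(tl$end_day)
    day_sets <- vapply(0:(horizon - 1), function(d) {
      paste(sort(unique(tl$drug_class[tl$start_day <= d & d < tl$end_day]),
                 method = "radix"), collapse = "+")
    }, "")
    r <- rle(day_sets)
    ends <- cumsum(r$lengths)
    seg <- data.frame(start_day = ends - r$lengths, end_day = ends,
                      classes = r$values, stringsAsFactors = FALSE)
    seg <- seg[seg$classes != "", , drop = FALSE]
    repeat {
      multi <- grepl("+", seg$classes, fixed = TRUE)
      dur <- seg$end_day - seg$start_day
      i <- which(dur < 30 & multi &
                   (c(FALSE, seg$end_day[-nrow(seg)] == seg$start_day[-1]) |
                      c(seg$start_day[-1] == seg$end_day[-nrow(seg)], FALSE)))
      if (length(i) == 0) break
      i <- i[1]
      if (i > 1 && seg$end_day[i - 1] == seg$start_day[i]) {
        seg$end_day[i - 1] <- seg$end_day[i]
      } else {
        seg$start_day[i + 1] <- seg$start_day[i]
      }
      seg <- seg[-i, , drop = FALSE]
      # re-merge equal contiguous neighbours
      k <- 1
      while (k < nrow(seg)) {
        if (seg$classes[k] == seg$classes[k + 1] &&
            seg$end_day[k] == seg$start_day[k + 1]) {
          seg$end_day[k] <- seg$end_day[k + 1]
          seg <- seg[-(k + 1), , drop = FALSE]
        } else k <- k + 1
      }
    }
    rownames(seg) <- NULL
    expect_equal(per$start_day, seg$start_day, info = paste("seed", seed))
    expect_equal(per$end_day, seg$end_day, info = paste("seed", seed))
    expect_equal(per$classes, seg$classes, info = paste("seed", seed))
    # periods tile the covered days exactly
    covered <- which(day_sets != "") - 1
    in_periods <- unlist(Map(seq, per$start_day, per$end_day - 1))
    expect_setequal(covered, in_periods)
  }
})

test_that("the belatacept algorithm applies its three clauses as specified", {
  cfg <- code_config()
  qual_stays <- function(days) {
    dplyr::bind_rows(lapply(days, function(d)
      mk_stay("a", d0 + d, adx = "Z940", chemo = TRUE)))
  }
  del_mpa <- mk_del("a", d0 + 10, "L04AA06")
  call1 <- detect_belatacept(qual_stays(c(0, 30, 60)), del_mpa, idx_a, cfg)
  expect_true(call1$positive)
  expect_equal(call1$source, "algorithm")
  expect_equal(call1$index_hosp_day, 0)

  # only two qualifying stays
  call2 <- detect_belatacept(qual_stays(c(0, 30)), del_mpa, idx_a, cfg)
  expect_false(call2$positive)
  expect_false(call2$three_stays)

  # three stays but spanning more than 90 days
  call3 <- detect_belatacept(qual_stays(c(0, 50, 100)), del_mpa, idx_a, cfg)
  expect_false(call3$positive)

  # no companion delivery within 90 days
  call4 <- detect_belatacept(qual_stays(c(0, 30, 60)),
                             mk_del("a", d0 + 120, "L04AA06"), idx_a, cfg)
  expect_false(call4$positive)
  expect_false(call4$companion)

  # CNI delivered in the fourth month vetoes
  call5 <- detect_belatacept(qual_stays(c(0, 30, 60)),
                             dplyr::bind_rows(del_mpa,
                                              mk_del("a", d0 + 100, "L04AD02")),
                             idx_a, cfg)
  expect_false(call5$positive)
  expect_false(call5$cni_free)
  # ... but a CNI just outside the window does not
  call6 <- detect_belatacept(qual_stays(c(0, 30, 60)),
                             dplyr::bind_rows(del_mpa,
                                              mk_del("a", d0 + 121, "L04AD02")),
                             idx_a, cfg)
  expect_true(call6$positive)

  # chemo stays without a transplant diagnosis never qualify
  onc <- dplyr::bind_rows(lapply(c(0, 30, 60), function(d)
    mk_stay("a", d0 + d, pdx = "C349", chemo = TRUE)))
  expect_false(detect_belatacept(onc, del_mpa, idx_a, cfg)$positive)

  # a belatacept-coded community delivery short-circuits to positive
  call7 <- detect_belatacept(empty_tbl("stays"),
                             mk_del("a", d0 + 400, "L04AA28"), idx_a, cfg)
  expect_true(call7$positive)
  expect_equal(call7$source, "direct_retrocession")
})

test_that("belatacept calls equal exhaustive triple enumeration on randomized streams", {
  cfg <- code_config()
  for (seed in 1:25) {
    set.seed(seed)
    n_stays <- sample(0:20, 1)
    stay_days <- sort(sample(0:300, n_stays))
    qual <- runif(n_stays) < 0.7
    stays <- dplyr::bind_rows(lapply(seq_len(n_stays), function(i)
      mk_stay("a", d0 + stay_days[i],
              adx = if (qual[i]) "Z940" else "", chemo = TRUE)))
    n_del <- sample(0:15, 1)
    del_days <- sample(0:300, n_del, replace = TRUE)
    del_atc <- sample(c("L04AA06", "L04AA18", "L04AD02", "H02AB06", "X"),
                      n_del, replace = TRUE)
    del <- mk_del("a", d0 + del_days, del_atc)
    if (n_stays == 0) stays <- empty_tbl("stays")
    if (n_del == 0) del <- empty_tbl("deliveries")
    got <- detect_belatacept(stays, del, idx_a, cfg)
    ora <- belatacept_oracle(
      stay_days[qual],
      data.frame(day = del_days,
                 group = roll_up_class(classify_atc(del_atc, cfg))),
      cfg)
    expect_equal(got$positive, ora$positive, info = paste("seed", seed))
    if (got$three_stays) {
      expect_equal(got$index_hosp_day, ora$hosp, info = paste("seed", seed))
    }
  }
})

test_that("switches and add-ons are classified by residual coverage of the prior class", {
  cfg <- code_config()
  # clean switch: tacrolimus stops, everolimus relays at day 200
  del <- dplyr::bind_rows(
    mk_del("a", d0 + seq(0, 180, 30), "L04AD02"),
    mk_del("a", d0 + seq(200, 400, 30), "L04AA18"))
  sw <- detect_switches(build_timeline(del, idx_a, cfg), cfg)
  expect_equal(nrow(sw), 1)
  expect_equal(sw$day, 200)
  expect_equal(sw$kind, "switch")
  expect_equal(sw$from_classes, "tacrolimus")
  expect_equal(sw$to_classes, "everolimus")

  # single-class stream: no events
  mono <- mk_del("a", d0 + seq(0, 400, 30), "L04AD02")
  expect_equal(nrow(detect_switches(build_timeline(mono, idx_a, cfg), cfg)), 0)

  # tacrolimus continues >= 30 d after everolimus starts: add-on
  del2 <- dplyr::bind_rows(
    mk_del("a", d0 + seq(0, 400, 30), "L04AD02"),
    mk_del("a", d0 + seq(200, 400, 30), "L04AA18"))
  sw2 <- detect_switches(build_timeline(del2, idx_a, cfg), cfg)
  expect_equal(sw2$kind, "add_on")
  expect_equal(sw2$from_classes, "tacrolimus")
  expect_equal(sw2$to_classes, "everolimus+tacrolimus")

  # exactly 30 residual days resolves as add-on (inclusive rule)
  del3 <- dplyr::bind_rows(
    mk_del("a", d0 + c(seq(0, 180, 30), 200), "L04AD02"),  # coverage to day 230
    mk_del("a", d0 + seq(200, 400, 30), "L04AA18"))
  sw3 <- detect_switches(build_timeline(del3, idx_a, cfg), cfg)
  expect_equal(sw3$kind, "add_on")

  # corticosteroid arrivals are not relay events
  del4 <- dplyr::bind_rows(
    mk_del("a", d0 + seq(0, 400, 30), "L04AD02"),
    mk_del("a", d0 + seq(200, 400, 30), "H02AB06"))
  expect_equal(nrow(detect_switches(build_timeline(del4, idx_a, cfg), cfg)), 0)

  # class arrivals inside the initial 90-day window build the initial regimen
  del5 <- dplyr::bind_rows(
    mk_del("a", d0 + seq(0, 400, 30), "L04AD02"),
    mk_del("a", d0 + seq(60, 400, 30), "L04AA06"))
  expect_equal(nrow(detect_switches(build_timeline(del5, idx_a, cfg), cfg)), 0)
})

test_that("initial regimens come from 90-day coverage plus belatacept calls", {
  cfg <- code_config()
  del <- dplyr::bind_rows(
    mk_del("a", d0 + c(0, 30), "L04AD02"),
    mk_del("a", d0 + c(0, 30), "L04AA06"),
    mk_del("a", d0 + c(0, 30), "H02AB06"))
  tl <- build_timeline(del, idx_a, cfg)
  none <- detect_belatacept(empty_tbl("stays"), del, idx_a, cfg)
  ir <- initial_regimen(tl, none, idx_a, cfg)
  expect_equal(ir$initial_groups, "CNI+antimetabolite+corticosteroid")

  # no deliveries and a negative call: empty regimen
  ir0 <- initial_regimen(tl[0, ], none, idx_a, cfg)
  expect_equal(ir0$initial_groups, "")

  # a positive call with an early index hospitalization adds belatacept
  stays <- dplyr::bind_rows(lapply(c(0, 30, 60), function(d)
    mk_stay("a", d0 + d, adx = "Z940", chemo = TRUE)))
  mpa <- mk_del("a", d0 + c(0, 30), "L04AA06")
  call <- detect_belatacept(stays, mpa, idx_a, cfg)
  ir2 <- initial_regimen(build_timeline(mpa, idx_a, cfg), call, idx_a, cfg)
  expect_equal(ir2$initial_groups, "antimetabolite+belatacept")
})

test_that("zero-noise cohorts recover initial regimens and switch dates exactly", {
  sim <- simulate_claims(sim_config(n_patients = 250, seed = 13))
  cfg <- sim$bundle$code_config
  idx <- dplyr::select(sim$truth, "patient_id", "index_date")
  del <- classify_deliveries(sim$bundle$deliveries, cfg)
  tl <- build_timeline(del, idx, cfg)
  calls <- detect_belatacept(sim$bundle$stays, del, idx, cfg)
  tl <- dplyr::bind_rows(tl, belatacept_episodes(sim$bundle$stays, calls, idx, cfg))

  ir <- initial_regimen(tl, calls, idx, cfg)
  truth_key <- truth_group_key(sim$truth$initial_regimen)
  m <- match(sim$truth$patient_id, ir$patient_id)
  expect_identical(ir$initial_groups[m], truth_key)

  sw <- detect_switches(tl, cfg)
  true_sw <- sim$truth_timeline[sim$truth_timeline$start_day > 0, ]
  expect_equal(nrow(sw), nrow(true_sw))
  key <- function(p, d) paste(p, d)
  got <- sort(key(sw$patient_id, sw$day))
  want <- sort(key(true_sw$patient_id, true_sw$start_day))
  expect_identical(got, want)
})
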