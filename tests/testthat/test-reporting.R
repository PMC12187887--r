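test_that("treatment table counts classes, molecules and combinations against era denominators", {
  cfg <- code_config()
  cohort <- tibble::tibble(patient_id = c("a", "b"),
                           index_date = as.Date(c("2010-05-01", "2017-03-01")),
                           index_year = c(2010L, 2017L))
  idx <- dplyr::select(cohort, "patient_id", "index_date")
  del <- dplyr::bind_rows(
    mk_del("a", as.Date("2010-05-01") + seq(0, 180, 30), "L04AD02"),
    mk_del("a", as.Date("2010-05-01") + seq(0, 180, 30), "L04AA06"),
    mk_del("a", as.Date("2011-05-01") + seq(0, 60, 30), "L04AD01"),
    mk_del("b", as.Date("2017-03-01") + seq(0, 90, 30), "L04AD02"))
  tl <- build_timeline(classify_deliveries(del, cfg), idx, cfg)
  reg <- detect_combinations(tl, cfg)
  calls <- detect_belatacept(empty_tbl("stays"),
                             classify_deliveries(del, cfg), idx, cfg)
  tt <- treatment_table(cohort, tl, reg, calls, cfg)

  pick <- function(era, treatment, level) {
    r <- tt[tt$era == era & tt$treatment == treatment & tt$level == level, ]
    if (nrow(r) == 0) 0L else r$n
  }
  # every patient delivered tacrolimus: CNI class row at 100%
  expect_equal(pick("overall", "CNI", "class"), 2L)
  expect_equal(tt$pct[tt$era == "overall" & tt$treatment == "CNI" &
                        tt$level == "class"], 100)
  # patient a took both CNI molecules: one CNI count, one per molecule row
  expect_equal(pick("overall", "tacrolimus", "molecule"), 2L)
  expect_equal(pick("overall", "ciclosporin", "molecule"), 1L)
  expect_equal(pick("2009-2011", "CNI", "class"), 1L)
  expect_equal(pick("2016-2019", "CNI", "class"), 1L)
  # only patient a sustained a recognized combination
  expect_equal(pick("overall", "CNI+antimetabolite", "combination"), 1L)
  # denominators are era cohort sizes
  expect_true(all(tt$denom[tt$era == "overall"] == 2))
  expect_true(all(tt$denom[tt$era == "2009-2011"] == 1))
})

test_that("index years outside the era buckets are excluded from the treatment table", {
  cfg <- code_config()
  cohort <- tibble::tibble(patient_id = c("a", "b"),
                           index_date = as.Date(c("2018-05-01", "2020-06-01")),
                           index_year = c(2018L, 2020L))
  del <- mk_del("a", as.Date("2018-05-02"), "L04AD02") |>
    dplyr::bind_rows(mk_del("b", as.Date("2020-06-02"), "L04AD02"))
  tl <- build_timeline(classify_deliveries(del, cfg),
                       dplyr::select(cohort, "patient_id", "index_date"), cfg)
  calls <- detect_belatacept(empty_tbl("stays"),
                             classify_deliveries(del, cfg),
                             dplyr::select(cohort, "patient_id", "index_date"),
                             cfg)
  tt <- treatment_table(cohort, tl, detect_combinations(tl, cfg), calls, cfg)
  expect_true(all(tt$denom[tt$era == "overall"] == 1))  # 2020 index excluded
})

test_that("yearly prevalence equals a brute-force year-bucketed distinct count", {
  cfg <- code_config()
  # deliveries every 30 d across a year boundary count in both years
  del <- mk_del("a", as.Date("2015-11-15") + seq(0, 120, 30), "L04AD02")
  calls <- detect_belatacept(empty_tbl("stays"), classify_deliveries(del, cfg),
                             tibble::tibble(patient_id = "a",
                                            index_date = as.Date("2015-11-15")),
                             cfg)
  yp <- yearly_prevalence(classify_deliveries(del, cfg), empty_tbl("stays"),
                          calls, cfg)
  tac <- yp[yp$treatment == "tacrolimus", ]
  expect_setequal(tac$year, c(2015L, 2016L))
  expect_true(all(tac$n_patients == 1))

  # randomized fixture vs group-by oracle
  set.seed(31)
  ids <- sprintf("p%02d", 1:12)
  del2 <- tibble::tibble(
    patient_id = sample(ids, 300, replace = TRUE),
    delivery_date = as.Date("2012-01-01") + sample(0:2000, 300, replace = TRUE),
    atc_code = sample(names(cfg$drug_class_map), 300, replace = TRUE),
    presentation_id = "")
  cd <- classify_deliveries(del2, cfg)
  calls2 <- tibble::tibble(patient_id = ids, positive = FALSE,
                           source = "none", index_hosp_day = NA_integer_,
                           three_stays = FALSE, companion = NA, cni_free = NA)
  yp2 <- yearly_prevalence(cd, empty_tbl("stays"), calls2, cfg)
  oracle <- cd |>
    dplyr::mutate(year = as.integer(format(delivery_date, "%Y"))) |>
    dplyr::distinct(patient_id, year, drug_class) |>
    dplyr::count(year, treatment = drug_class, name = "n_patients")
  got <- yp2[yp2$level == "molecule", c("year", "treatment", "n_patients")]
  expect_equal(dplyr::arrange(got, year, treatment),
               dplyr::arrange(oracle, year, treatment))
})

test_that("the switch matrix cross-tabulates relays and the never-switched fraction", {
  cohort <- tibble::tibble(patient_id = c("a", "b", "c"))
  none <- tibble::tibble(patient_id = character(), day = integer(),
                         from_classes = character(), to_classes = character(),
                         kind = character(), order = integer())
  sm0 <- switch_matrix(none, cohort)
  expect_equal(sm0$never_switched_frac, 1)
  expect_equal(nrow(sm0$transitions), 0)

  ev <- tibble::tibble(
    patient_id = c("a", "a", "b"),
    day = c(200L, 600L, 300L),
    from_classes = c("tacrolimus", "everolimus", "tacrolimus"),
    to_classes = c("everolimus", "tacrolimus", "everolimus"),
    kind = "switch", order = c(1L, 2L, 1L))
  sm <- switch_matrix(ev, cohort)
  expect_equal(sm$n_switchers, 2)
  expect_equal(sm$n_multi_switchers, 1)
  expect_equal(sm$never_switched_frac, 1 / 3)
  first_tac_ev <- sm$transitions[sm$transitions$relay == "first" &
                                   sm$transitions$from_classes == "tacrolimus", ]
  expect_equal(first_tac_ev$n, 2L)
})

test_that("simulated switch totals track the configured switching intensity", {
  n <- 1500
  cfg <- sim_config(n_patients = n, seed = 23)
  sim <- simulate_claims(cfg)
  rep <- run_pipeline(sim$bundle)
  # truth-derived expectation: detected switch count equals true switch count
  expect_equal(nrow(rep$switches), sum(sim$truth$n_switches))
  # and the per-patient switch intensity is consistent with switch_rate:
  # switches need a year-long minimum gap, so compare against the truth count
  # rather than a closed form; determinism of the pair is the contract here
  expect_equal(rep$switch_summary$n_switchers,
               sum(sim$truth$n_switches > 0))
})

test_that("the full pipeline is deterministic and handles empty cohorts", {
  sim <- simulate_claims(sim_config(n_patients = 60, seed = 3))
  r1 <- run_pipeline(sim$bundle)
  r2 <- run_pipeline(sim$bundle)
  for (tb in c("cohort", "baseline", "timeline", "regimens", "belatacept",
               "switches", "initial_regimens", "outcomes", "outcome_table",
               "treatment", "prevalence")) {
    expect_identical(r1[[tb]], r2[[tb]], info = tb)
  }
  expect_identical(r1$switch_summary, r2$switch_summary)

  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  write_report_set(r1, dir1); write_report_set(r2, dir2)
  for (f in list.files(dir1)) {
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)), info = f)
  }

  # an input with no eligible patients yields empty tables, not an error
  b <- mk_bundle(patients = mk_patients("a"),
                 deliveries = mk_del("a", "2015-01-01", "L04AD02"))
  r0 <- run_pipeline(b)
  expect_equal(nrow(r0$cohort), 0)
  expect_equal(nrow(r0$outcomes), 0)
  expect_equal(nrow(r0$treatment), 0)
})

test_that("simulate -> write -> read -> pipeline reproduces the in-memory run", {
  sim <- simulate_claims(sim_config(n_patients = 40, seed = 77))
  dir <- withr::local_tempdir()
  write_bundle(sim$bundle, dir)
  b2 <- read_bundle(dir)
  r_mem <- run_pipeline(sim$bundle)
  r_csv <- run_pipeline(b2)
  expect_equal(r_csv$outcomes, r_mem$outcomes)
  expect_equal(r_csv$treatment, r_mem$treatment)
})
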