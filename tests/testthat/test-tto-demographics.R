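mini_cohort <- function(event_dt, start_dt) {
  n <- length(event_dt)
  cases <- tibble::tibble(
    caseid = as.character(seq_len(n)), primaryid = as.character(seq_len(n)),
    fda_dt = "20240101", event_dt = event_dt, sex = "F", age_years = 20,
    age_group = "18-65", reporter_class = "Physician", country = "US",
    outcomes = rep(list(character()), n),
    indications = rep(list(character()), n),
    events = rep(list(tibble::tibble(pt = character(), soc = character(),
                                     is_ime = logical(),
                                     is_unlabeled = logical())), n)
  )
  drug <- tibble::tibble(primaryid = cases$primaryid, caseid = cases$caseid,
                         drug_seq = 1L, role_cod = "PS",
                         drugname = "ISOTRETINOIN", prod_ai = NA_character_)
  ther <- tibble::tibble(primaryid = cases$primaryid, caseid = cases$caseid,
                         dsg_drug_seq = 1L, start_dt = start_dt,
                         end_dt = NA_character_)
  list(cases = cases, drug = drug, ther = ther)
}

test_that("onset is the calendar-day difference with the stated exclusions", {
  cohort <- mini_cohort(
    event_dt = c("20200401", "20200201", "20200301", "202005", NA),
    start_dt = c("20200101", "20200301", NA, "20200101", "20200101")
  )
  tto <- compute_tto(cohort$cases, cohort$drug, cohort$ther, "ISOTRETINOIN")
  expect_equal(tto$onset_days[1], 91L)    # leap year: 31 + 29 + 31
  expect_true(tto$included[1])
  expect_equal(tto$exclusion_reason[2], "negative")
  expect_equal(tto$exclusion_reason[3], "missing_date")
  # partial event date is unusable at day resolution
  expect_equal(tto$exclusion_reason[4], "missing_date")
  expect_equal(tto$exclusion_reason[5], "missing_date")
  expect_true(all(is.na(tto$onset_days[!tto$included])))
})

test_that("the earliest therapy start among target rows bounds onset", {
  cohort <- mini_cohort("20200301", "20200201")
  cohort$drug <- dplyr::bind_rows(
    cohort$drug,
    tibble::tibble(primaryid = "1", caseid = "1", drug_seq = 2L,
                   role_cod = "SS", drugname = "ISOTRETINOIN",
                   prod_ai = NA_character_)
  )
  cohort$ther <- dplyr::bind_rows(
    cohort$ther,
    tibble::tibble(primaryid = "1", caseid = "1", dsg_drug_seq = 2L,
                   start_dt = "20200101", end_dt = NA_character_)
  )
  tto <- compute_tto(cohort$cases, cohort$drug, cohort$ther, "ISOTRETINOIN")
  expect_equal(tto$onset_days, 60L)
})

test_that("onset summaries bin and interpolate as specified", {
  rec <- function(days) {
    tibble::tibble(caseid = as.character(seq_along(days)),
                   primaryid = as.character(seq_along(days)),
                   onset_days = as.integer(days), included = TRUE,
                   exclusion_reason = "none")
  }
  s1 <- summarize_tto(rec(5))
  expect_equal(s1$bins$count, c(1L, 0L, 0L, 0L, 0L, 0L))
  expect_equal(s1$bins$proportion[1], 1)

  s2 <- summarize_tto(rec(c(10, 45, 100, 200, 400)))
  expect_equal(s2$bins$count, c(1L, 1L, 0L, 1L, 1L, 1L))

  s3 <- summarize_tto(rec(c(31, 81, 169)))
  expect_equal(s3$median_days, 81)
  expect_equal(s3$q1, (31 + 81) / 2)

  expect_equal(sum(s2$bins$count), s2$n_included)
  expect_equal(sum(s2$bins$proportion), 1, tolerance = 1e-9)
  expect_error(summarize_tto(rec(5), bin_edges = c(60, 30)), "bin_edges")
})

test_that("exclusion accounting always balances", {
  sim <- simulate_faers(sim_config(n_cases = 3000, seed = 12,
                                   negative_onset_rate = 0.1))
  lk <- tiny_lookups()
  retained <- dedup_reports(sim$tables$demo)
  selected <- select_drug_reports(sim$tables$drug, lk$synonyms)
  cases <- suppressWarnings(build_clean_cases(sim$tables, lk, retained, selected))
  tto <- compute_tto(cases, sim$tables$drug, sim$tables$ther, lk$synonyms)
  s <- summarize_tto(tto)
  expect_equal(s$n_included + s$n_missing_date + s$n_negative, nrow(cases))
  expect_gt(s$n_negative, 0)
})

test_that("the empirical median tracks the designed onset distribution", {
  # onset ~ lognormal(log 81, sd); order-statistic CI of the median over the
  # included records should cover 81 in most replicates
  hits <- vapply(1:10, function(s) {
    sim <- simulate_faers(sim_config(
      n_cases = 1500, seed = 400 + s, missing_start_rate = 0,
      missing_event_rate = 0, negative_onset_rate = 0, partial_date_rate = 0
    ))
    lk <- tiny_lookups()
    cases <- suppressWarnings(build_clean_cases(
      sim$tables, lk, dedup_reports(sim$tables$demo),
      select_drug_reports(sim$tables$drug, lk$synonyms)
    ))
    tto <- compute_tto(cases, sim$tables$drug, sim$tables$ther, lk$synonyms)
    days <- sort(tto$onset_days[tto$included])
    n <- length(days)
    loi <- max(1, qbinom(0.025, n, 0.5))
    hii <- min(n, qbinom(0.975, n, 0.5) + 1)
    days[loi] <= 81 && 81 <= days[hii]
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("demographic percentages use the case denominator, one decimal", {
  cases <- mini_cohort(rep("20200401", 4), rep("20200101", 4))$cases
  cases$sex <- c("F", "F", "F", "M")
  cases$fda_dt <- c("20200101", "20200601", "202103", "20220101")
  cases$outcomes <- list(c("DE", "HO"), "HO", character(), character())
  d <- summarize_demographics(cases)
  sex <- d[d$characteristic == "sex", ]
  expect_equal(sex$n[sex$level == "F"], 3L)
  expect_equal(sex$pct[sex$level == "F"], 75.0)
  expect_equal(sex$pct[sex$level == "M"], 25.0)
  # sex percentages sum to 100 within rounding
  expect_equal(sum(sex$pct), 100, tolerance = 0.1)
  # outcomes: multi-valued, so a case counts in each of its outcome rows
  outc <- d[d$characteristic == "outcome", ]
  expect_equal(outc$n[outc$level == "Death"], 1L)
  expect_equal(outc$n[outc$level == "Hospitalization"], 2L)
  expect_equal(outc$n[outc$level == "Missing"], 2L)
  # partial fda_dt still contributes its year
  yr <- d[d$characteristic == "year", ]
  expect_setequal(yr$level, c("2020", "2021", "2022"))
  expect_equal(yr$n[yr$level == "2020"], 2L)
})

test_that("an empty case set yields zero counts with undefined percentages", {
  sim <- simulate_faers(sim_config(n_cases = 10, seed = 2))
  cases <- build_clean_cases(sim$tables, tiny_lookups(), character(), character())
  d <- summarize_demographics(cases)
  expect_true(all(d$n == 0))
  expect_true(all(is.na(d$pct)))
})

test_that("single-valued characteristic percentages sum to ~100 on real-shaped data", {
  sim <- simulate_faers(sim_config(n_cases = 2000, seed = 77))
  lk <- tiny_lookups()
  cases <- suppressWarnings(build_clean_cases(
    sim$tables, lk, dedup_reports(sim$tables$demo),
    select_drug_reports(sim$tables$drug, lk$synonyms)
  ))
  d <- summarize_demographics(cases)
  for (ch in c("sex", "age_group", "reporter")) {
    expect_equal(sum(d$pct[d$characteristic == ch]), 100, tolerance = 0.2,
                 label = ch)
  }
})
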