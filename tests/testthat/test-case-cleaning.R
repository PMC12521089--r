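demo_of <- function(...) {
  m <- matrix(c(...), ncol = 3, byrow = TRUE)
  tibble::tibble(caseid = m[, 1], fda_dt = m[, 2], primaryid = m[, 3])
}

test_that("deduplication keeps the most recent version, then the higher id", {
  expect_equal(
    dedup_reports(demo_of("100", "20200101", "1", "100", "20200301", "2")),
    "2"
  )
  expect_equal(
    dedup_reports(demo_of("100", "20200101", "5", "100", "20200101", "9")),
    "9"
  )
  expect_equal(dedup_reports(demo_of("7", "20210101", "3")), "3")
  expect_equal(dedup_reports(demo_of("7", "20210101", "3")[0, ]), character())
})

test_that("a missing FDA_DT sorts below any dated version", {
  expect_equal(
    dedup_reports(demo_of("100", NA, "99", "100", "20050101", "1")),
    "1"
  )
  # both missing: higher primaryid wins
  expect_equal(dedup_reports(demo_of("100", NA, "2", "100", NA, "7")), "7")
})

test_that("deduplication is idempotent", {
  sim <- simulate_faers(sim_config(n_cases = 300, dup_rate = 0.5, seed = 21))
  kept <- dedup_reports(sim$tables$demo)
  again <- dedup_reports(sim$tables$demo[sim$tables$demo$primaryid %in% kept, ])
  expect_setequal(kept, again)
  expect_equal(length(kept), dplyr::n_distinct(sim$tables$demo$caseid))
})

test_that("deduplication recovers the simulation ledger exactly", {
  sim <- simulate_faers(sim_config(n_cases = 800, dup_rate = 0.4, seed = 13))
  kept <- dedup_reports(sim$tables$demo)
  truth <- sim$truth$dedup_ledger$primaryid[sim$truth$dedup_ledger$retain]
  expect_setequal(kept, truth)
})

test_that("drug selection honours synonyms, roles and matching mode", {
  drug <- tibble::tibble(
    primaryid = c("1", "2", "3", "4", "5"),
    caseid = as.character(1:5),
    drug_seq = 1L,
    role_cod = c("PS", "C", "PS", "SS", "PS"),
    drugname = c("ACCUTANE", "ACCUTANE", "aspirin", "ISOTRETINOIN",
                 "ISOTRETINOIN 20MG"),
    prod_ai = c(NA, NA, NA, "ISOTRETINOIN", NA)
  )
  syn <- c("ACCUTANE", "ISOTRETINOIN")
  expect_setequal(select_drug_reports(drug, syn), "1")         # PS + exact
  expect_setequal(select_drug_reports(drug, syn, required_role = NULL),
                  c("1", "2", "4"))
  expect_setequal(select_drug_reports(drug, syn, match = "substring"),
                  c("1", "5"))
  expect_equal(select_drug_reports(drug[0, ], syn), character())
  expect_error(select_drug_reports(drug, character()), "synonym")
})

test_that("event standardisation maps SOCs and flags IME / unlabeled terms", {
  lk <- tiny_lookups()
  reac <- tibble::tibble(
    primaryid = c("1", "1", "2", "2", "3"),
    caseid = c("1", "1", "2", "2", "3"),
    pt = c("Inflammatory bowel disease", "inflammatory BOWEL disease ",
           "Lip dry", "Unheard of event", "Nausea")
  )
  expect_warning(ev <- standardize_events(reac, lk), "UNMAPPED")
  # duplicate PT within a report collapses to one row
  expect_equal(nrow(ev), 4)
  ibd <- ev[ev$primaryid == "1", ]
  expect_equal(ibd$soc, "Gastrointestinal disorders")
  expect_true(ibd$is_ime)
  expect_false(ibd$is_unlabeled)   # on the label fixture
  expect_equal(ev$soc[ev$pt == "Unheard of event"], "UNMAPPED")
  expect_true(ev$is_unlabeled[ev$pt == "Nausea"])
})

test_that("age units normalise to years and bin half-open", {
  expect_equal(age_in_years(204, "MON"), 17)
  expect_equal(age_in_years(2, "DEC"), 20)
  expect_equal(age_in_years(365.25, "DY"), 1)
  expect_equal(faersignal:::age_group_of(c(17.99, 18, 65, 66, 85, 86, NA)),
               c("<18", "18-65", "18-65", "66-85", "66-85", ">85", "missing"))
})

test_that("clean cases assemble one row per selected, retained case", {
  sim <- simulate_faers(sim_config(n_cases = 2000, dup_rate = 0.3, seed = 8))
  lk <- tiny_lookups()
  retained <- dedup_reports(sim$tables$demo)
  selected <- select_drug_reports(sim$tables$drug, lk$synonyms)
  cases <- suppressWarnings(
    build_clean_cases(sim$tables, lk, retained, selected)
  )
  expect_equal(nrow(cases), dplyr::n_distinct(cases$caseid))
  expect_lte(nrow(cases), dplyr::n_distinct(sim$tables$demo$caseid))
  expect_setequal(cases$primaryid, intersect(retained, selected))
  expect_true(all(cases$age_group %in%
                    c("<18", "18-65", "66-85", ">85", "missing")))
  # every nested event maps to exactly one SOC
  ev <- case_events(cases)
  expect_false(any(is.na(ev$soc)))
  # a case with events has >= 1 event row
  expect_true(all(vapply(cases$events, nrow, integer(1)) >= 1))
})

test_that("empty intersections give an empty, well-typed case table", {
  sim <- simulate_faers(sim_config(n_cases = 20, seed = 9))
  cases <- build_clean_cases(sim$tables, tiny_lookups(),
                             retained_ids = character(),
                             selected_ids = character())
  expect_equal(nrow(cases), 0)
  expect_true(all(c("caseid", "age_group", "events") %in% names(cases)))
})
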