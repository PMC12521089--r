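test_that("contingency counts follow the distinct (report, term) pair rule", {
  events <- tibble::tibble(
    primaryid = c("r1", "r1", "r2"),
    pt = c("X", "Y", "X"),
    is_target = c(TRUE, TRUE, FALSE)
  )
  ct <- build_contingency(events, level = "pt")
  x <- ct[ct$term == "X", ]
  expect_equal(c(x$a, x$b, x$c, x$d), c(1L, 1L, 1L, 0L))
  # a term never co-occurring with the target drug is suppressed
  events2 <- dplyr::bind_rows(events,
                              tibble::tibble(primaryid = "r3", pt = "Z",
                                             is_target = FALSE))
  expect_false("Z" %in% build_contingency(events2, level = "pt")$term)
  # duplicated PT within one report counts once
  events3 <- dplyr::bind_rows(events,
                              tibble::tibble(primaryid = "r1", pt = "X",
                                             is_target = TRUE))
  expect_identical(build_contingency(events3, level = "pt"), ct)
})

test_that("report-level counting uses reports, not pairs, as the unit", {
  events <- tibble::tibble(
    primaryid = c("r1", "r1", "r2"),
    pt = c("X", "Y", "X"),
    is_target = c(TRUE, TRUE, FALSE)
  )
  ct <- build_contingency(events, level = "pt", counting = "report")
  x <- ct[ct$term == "X", ]
  # 2 reports total: target r1 has X, other r2 has X
  expect_equal(c(x$a, x$b, x$c, x$d), c(1L, 0L, 1L, 0L))
})

test_that("ROR and its Wald interval match direct arithmetic", {
  r <- compute_ror(3, 7, 97, 893)
  expect_equal(r$ror, 2679 / 679, tolerance = 1e-12)
  se <- sqrt(1 / 3 + 1 / 7 + 1 / 97 + 1 / 893)
  expect_equal(r$ror_lo, exp(log(2679 / 679) - qnorm(0.975) * se),
               tolerance = 1e-12)
  expect_equal(r$ror_hi, exp(log(2679 / 679) + qnorm(0.975) * se),
               tolerance = 1e-12)
  expect_equal(round(r$ror_lo, 2), 1.00)
  expect_equal(round(r$ror_hi, 1), 15.5)
  # symmetric table: ROR 1, CI straddles 1
  s <- compute_ror(10, 10, 10, 10)
  expect_equal(s$ror, 1)
  expect_lt(s$ror_lo, 1); expect_gt(s$ror_hi, 1)
})

test_that("a zero cell triggers the Haldane correction and keeps ROR finite", {
  r <- compute_ror(3, 0, 97, 900)
  expect_true(is.finite(r$ror))
  expect_equal(r$ror, (3.5 * 900.5) / (0.5 * 97.5), tolerance = 1e-12)
  # tables with all cells positive are untouched
  expect_equal(compute_ror(3, 7, 97, 893)$ror, 2679 / 679, tolerance = 1e-12)
})

test_that("PRR and Pearson chi-squared match direct arithmetic", {
  p <- compute_prr(3, 7, 97, 893)
  expect_equal(p$prr, 0.3 / (97 / 990), tolerance = 1e-12)
  expect_equal(p$chi2, 1000 * (2679 - 679)^2 / (10 * 990 * 100 * 900),
               tolerance = 1e-12)
  expect_equal(round(p$prr, 3), 3.062)
  expect_equal(round(p$chi2, 3), 4.489)
  null <- compute_prr(10, 10, 10, 10)
  expect_equal(null$prr, 1)
  expect_equal(null$chi2, 0)
  # Yates correction shrinks the statistic
  expect_lt(compute_prr(3, 7, 97, 893, yates = TRUE)$chi2, p$chi2)
})

test_that("BCPNN information component behaves at its reference points", {
  # a = 0 with large margins: negative association
  expect_lt(compute_bcpnn(0, 100, 100, 9800)$ic, 0)
  # independence at large N: shrinkage bias vanishes
  expect_lt(abs(compute_bcpnn(100, 900, 900, 8100)$ic), 0.05)
  # lower bound below the point estimate, everywhere
  set.seed(1)
  a <- rpois(50, 20) + 1; b <- rpois(50, 100); c <- rpois(50, 100)
  d <- rpois(50, 5000)
  bc <- compute_bcpnn(a, b, c, d)
  expect_true(all(bc$ic025 <= bc$ic))
})

test_that("the information component approaches its large-N limit", {
  scale <- 1e6 / 10000
  a <- 30 * scale; b <- 970 * scale; c <- 2970 * scale; d <- 6030 * scale
  n <- a + b + c + d
  limit <- log2(a * n / ((a + b) * (a + c)))
  expect_lt(abs(compute_bcpnn(a, b, c, d)$ic - limit), 0.01)
})

test_that("significance criteria and consensus follow the four-method rule", {
  mk <- function(n, ror_lo, prr, chi2, ic025, ebgm, ebgm05 = ebgm * 0.9) {
    tibble::tibble(n = n, ror_lo = ror_lo, prr = prr, chi2 = chi2,
                   ic025 = ic025, ebgm = ebgm, ebgm05 = ebgm05)
  }
  # values of a strong published-style signal: every flag on
  strong <- apply_criteria(mk(4570, 471.69, 474.43, 1019716.35, 6.14, 224.57))
  expect_true(all(strong$ror_sig, strong$prr_sig, strong$bcpnn_sig,
                  strong$ebgm_sig, strong$consensus))
  # fewer than 3 reports fails the ROR criterion regardless of the interval
  few <- apply_criteria(mk(2, 50, 474, 1000, 6, 200))
  expect_false(few$ror_sig)
  expect_false(few$consensus)
  # all-null statistics: nothing flags
  null <- apply_criteria(mk(10, 0.8, 1, 0, -1, 1))
  expect_false(any(null$ror_sig, null$prr_sig, null$bcpnn_sig,
                   null$ebgm_sig, null$consensus))
  # missing statistics fail their flag rather than erroring
  na_case <- apply_criteria(mk(10, NA, 3, 10, 1, 3))
  expect_false(na_case$ror_sig)
  expect_true(na_case$prr_sig)
  # EBGM05 gating is the conservative switch
  eb <- mk(10, 2, 3, 10, 1, ebgm = 2.5, ebgm05 = 1.5)
  expect_true(apply_criteria(eb)$ebgm_sig)
  expect_false(apply_criteria(eb, criteria_config(ebgm_stat = "EBGM05"))$ebgm_sig)
})

test_that("weakening any threshold never turns a positive term negative", {
  sim <- simulate_faers(signal_cfg(3000, multiplier = 6, seed = 31, dup_rate = 0))
  universe <- suppressWarnings(
    standardize_events(sim$tables$reac, tiny_lookups())
  )
  sel <- select_drug_reports(sim$tables$drug, "ISOTRETINOIN")
  universe$is_target <- universe$primaryid %in% sel
  base <- detect_signals(universe, level = "pt")
  weaker <- list(
    criteria_config(min_count = 1),
    criteria_config(prr_min = 1),
    criteria_config(chi2_min = 0),
    criteria_config(ic025_min = -1),
    criteria_config(ebgm_min = 1)
  )
  for (cfg in weaker) {
    relaxed <- apply_criteria(base, cfg)
    expect_true(all(relaxed$consensus[base$consensus]))
  }
})

test_that("pipeline statistics equal brute-force pair enumeration exactly", {
  sim <- simulate_faers(signal_cfg(1000, multiplier = 4, seed = 17, dup_rate = 0))
  universe <- suppressWarnings(
    standardize_events(sim$tables$reac, tiny_lookups())
  )
  sel <- select_drug_reports(sim$tables$drug, "ISOTRETINOIN")
  universe$is_target <- universe$primaryid %in% sel
  sig <- detect_signals(universe, level = "pt")
  oracle <- brute_force_stats(universe)
  m <- merge(as.data.frame(sig), oracle, by = "term",
             suffixes = c("", "_bf"))
  expect_equal(nrow(m), nrow(sig))
  expect_identical(as.numeric(m$a), m$a_bf)
  expect_identical(as.numeric(m$b), m$b_bf)
  expect_identical(as.numeric(m$c), m$c_bf)
  expect_identical(as.numeric(m$d), m$d_bf)
  expect_equal(m$ror, m$ror_bf, tolerance = 1e-12)
  expect_equal(m$prr, m$prr_bf, tolerance = 1e-12)
  expect_equal(m$chi2, m$chi2_bf, tolerance = 1e-12)
})
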