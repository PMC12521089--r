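#' Default drug and event catalogs for the synthetic generator
#'
#' The default study conditions: one target drug (an isotretinoin-like
#' product, always primary suspect, used in 10% of reports) against five
#' background drugs with mixed role codes, and 24 MedDRA-style Preferred
#' Terms whose per-report background probabilities sum to about 2, so the
#' average report carries about two distinct events.
#'
#' @return `default_drug_catalog()`: a tibble with columns `drug`, `p_use`
#'   (probability a report mentions the drug) and role frequencies `p_ps`,
#'   `p_ss`, `p_c`, `p_i`. `default_pt_catalog()`: a tibble with columns
#'   `pt`, `soc`, `p_event` (per-report background event probability).
#' @export
default_drug_catalog <- function() {
  tibble(
    drug  = c("ISOTRETINOIN", "DRUG ALPHA", "DRUG BRAVO", "DRUG CHARLIE",
              "DRUG DELTA", "DRUG ECHO"),
    p_use = c(0.10, 0.30, 0.30, 0.25, 0.25, 0.20),
    p_ps  = c(1.00, 0.50, 0.50, 0.50, 0.50, 0.50),
    p_ss  = c(0.00, 0.20, 0.20, 0.20, 0.20, 0.20),
    p_c   = c(0.00, 0.25, 0.25, 0.25, 0.25, 0.25),
    p_i   = c(0.00, 0.05, 0.05, 0.05, 0.05, 0.05)
  )
}

#' @rdname default_drug_catalog
#' @export
default_pt_catalog <- function() {
  tibble(
    pt = c(
      "Inflammatory bowel disease", "Lip dry", "Cheilitis", "Nausea",
      "Headache", "Depression", "Suicidal ideation", "Rash", "Dry skin",
      "Arthralgia", "Myalgia", "Blood triglycerides increased",
      "Vision blurred", "Dry eye", "Fatigue", "Dizziness", "Vomiting",
      "Diarrhoea", "Pruritus", "Alopecia", "Epistaxis", "Back pain",
      "Insomnia", "Anxiety"
    ),
    soc = c(
      "Gastrointestinal disorders", "Gastrointestinal disorders",
      "Gastrointestinal disorders", "Gastrointestinal disorders",
      "Nervous system disorders", "Psychiatric disorders",
      "Psychiatric disorders", "Skin and subcutaneous tissue disorders",
      "Skin and subcutaneous tissue disorders",
      "Musculoskeletal and connective tissue disorders",
      "Musculoskeletal and connective tissue disorders", "Investigations",
      "Eye disorders", "Eye disorders",
      "General disorders and administration site conditions",
      "Nervous system disorders", "Gastrointestinal disorders",
      "Gastrointestinal disorders", "Skin and subcutaneous tissue disorders",
      "Skin and subcutaneous tissue disorders",
      "Respiratory, thoracic and mediastinal disorders",
      "Musculoskeletal and connective tissue disorders",
      "Psychiatric disorders", "Psychiatric disorders"
    ),
    p_event = c(
      0.02, 0.04, 0.04, 0.20, 0.18, 0.08, 0.03, 0.15, 0.06,
      0.10, 0.08, 0.03, 0.04, 0.04, 0.15, 0.12, 0.10, 0.12, 0.08,
      0.05, 0.03, 0.10, 0.08, 0.08
    )
  )
}

#' Configuration of the synthetic FAERS generator
#'
#' Defines the study conditions for a simulated spontaneous-report dataset:
#' how many unique cases, which drugs and events exist with what background
#' rates, which drug-event pairs carry a designed reporting-rate multiplier,
#' and the rates of the data pathologies the cleaning stages must handle
#' (duplicate case versions, missing and partial dates, negative onset
#' intervals).
#'
#' @param n_cases Number of unique cases (>= 1).
#' @param drug_catalog Tibble as [default_drug_catalog()].
#' @param pt_catalog Tibble as [default_pt_catalog()].
#' @param signal_spec Tibble with columns `drug`, `pt`, `multiplier`
#'   (>= 0): the designed reporting-rate multipliers. A report mentioning
#'   `drug` carries `pt` with probability `min(1, p_event * multiplier)`;
#'   a multiplier of 0 guarantees the pair never co-occurs.
#' @param dup_rate Probability a case emits a second, later version.
#' @param missing_start_rate,missing_event_rate Probability the therapy
#'   start / the event date is blanked.
#' @param negative_onset_rate Probability start and event dates are swapped,
#'   producing a negative onset interval.
#' @param partial_date_rate Probability a surviving event/start date is
#'   truncated to a 6-digit (YYYYMM) or 4-digit (YYYY) partial date.
#' @param date_window Length-2 [Date] vector: earliest and latest therapy
#'   start dates.
#' @param onset_meanlog,onset_sdlog Log-normal parameters of the simulated
#'   onset interval in days (defaults give median 81 days, quartiles near
#'   31 and 169).
#' @param seed Integer seed; identical config + seed reproduce byte-identical
#'   tables.
#' @return A validated object of class `sim_config`.
#' @export
sim_config <- function(n_cases = 10000,
                       drug_catalog = default_drug_catalog(),
                       pt_catalog = default_pt_catalog(),
                       signal_spec = NULL,
                       dup_rate = 0.05,
                       missing_start_rate = 0.3,
                       missing_event_rate = 0.3,
                       negative_onset_rate = 0.02,
                       partial_date_rate = 0.05,
                       date_window = as.Date(c("2004-01-01", "2024-06-30")),
                       onset_meanlog = log(81),
                       onset_sdlog = log(169 / 31) / (2 * stats::qnorm(0.75)),
                       seed = 1L) {
  if (is.null(signal_spec)) {
    signal_spec <- tibble(drug = character(), pt = character(),
                          multiplier = numeric())
  }
  signal_spec <- as_tibble(signal_spec)
  drug_catalog <- as_tibble(drug_catalog)
  pt_catalog <- as_tibble(pt_catalog)

  chk_prob <- function(x, field) {
    if (any(!is.finite(x) | x < 0 | x > 1)) {
      stop("configuration error: '", field, "' must be a probability in [0, 1]",
           call. = FALSE)
    }
  }
  if (length(n_cases) != 1 || is.na(n_cases) || n_cases < 1) {
    stop("configuration error: 'n_cases' must be a positive integer", call. = FALSE)
  }
  chk_prob(drug_catalog$p_use, "drug_catalog$p_use")
  role_sum <- drug_catalog$p_ps + drug_catalog$p_ss + drug_catalog$p_c + drug_catalog$p_i
  if (any(abs(role_sum - 1) > 1e-8)) {
    stop("configuration error: role frequencies in 'drug_catalog' must sum to 1",
         call. = FALSE)
  }
  chk_prob(pt_catalog$p_event, "pt_catalog$p_event")
  chk_prob(dup_rate, "dup_rate")
  chk_prob(missing_start_rate, "missing_start_rate")
  chk_prob(missing_event_rate, "missing_event_rate")
  chk_prob(negative_onset_rate, "negative_onset_rate")
  chk_prob(partial_date_rate, "partial_date_rate")
  if (nrow(signal_spec) > 0) {
    if (any(!is.finite(signal_spec$multiplier) | signal_spec$multiplier < 0)) {
      stop("configuration error: 'signal_spec$multiplier' must be >= 0", call. = FALSE)
    }
    bad_drug <- setdiff(signal_spec$drug, drug_catalog$drug)
    if (length(bad_drug) > 0) {
      stop("configuration error: 'signal_spec$drug' not in drug_catalog: ",
           paste(bad_drug, collapse = ", "), call. = FALSE)
    }
    bad_pt <- setdiff(signal_spec$pt, pt_catalog$pt)
    if (length(bad_pt) > 0) {
      stop("configuration error: 'signal_spec$pt' not in pt_catalog: ",
           paste(bad_pt, collapse = ", "), call. = FALSE)
    }
  }
  structure(
    list(
      n_cases = as.integer(n_cases), drug_catalog = drug_catalog,
      pt_catalog = pt_catalog, signal_spec = signal_spec,
      dup_rate = dup_rate, missing_start_rate = missing_start_rate,
      missing_event_rate = missing_event_rate,
      negative_onset_rate = negative_onset_rate,
      partial_date_rate = partial_date_rate,
      date_window = as.Date(date_window),
      onset_meanlog = onset_meanlog, onset_sdlog = onset_sdlog,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# sample one PT index per row of a probability matrix (rows needing a
# forced event); rows whose weights are all zero return NA
sample_weighted_rows <- function(q) {
  vapply(seq_len(nrow(q)), function(i) {
    w <- q[i, ]
    if (sum(w) <= 0) return(NA_integer_)
    sample.int(length(w), 1L, prob = w)
  }, integer(1))
}

#' Generate a synthetic FAERS-style dataset with known ground truth
#'
#' Draws a linked multi-table spontaneous-report dataset in the FAERS
#' quarterly dialect. Each case carries one DEMO row per version, at least
#' one DRUG row with a role code, at least one REAC row (one or more distinct
#' Preferred Terms), THER rows with therapy dates, and probabilistic OUTC and
#' INDI rows. Events are drawn per (report, PT) as independent Bernoulli
#' trials with probability `min(1, p_event * multiplier)`, so a designed
#' multiplier is, by construction, the asymptotic pair-level reporting odds
#' ratio the downstream analysis should recover. Duplicate case versions are
#' then injected via [inject_duplicates()].
#'
#' @param config A [sim_config()].
#' @return A list with elements
#'   \describe{
#'     \item{tables}{named list of tibbles `demo`, `drug`, `reac`, `ther`,
#'       `outc`, `indi`;}
#'     \item{truth}{a `sim_truth` list: `signal_counts` (the realized
#'       pair-level 2x2 counts `a`, `b`, `c`, `d` for every designed pair),
#'       `dedup_ledger` (one row per emitted DEMO version with the version
#'       that must survive deduplication), and the `config`.}
#'   }
#' @examples
#' sim <- simulate_faers(sim_config(n_cases = 200, dup_rate = 0, seed = 7))
#' nrow(sim$tables$demo)
#' @export
simulate_faers <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_cases
  dc <- config$drug_catalog
  pc <- config$pt_catalog
  K <- nrow(dc)
  P <- nrow(pc)

  caseid_num <- 10000000L + seq_len(n)
  caseid <- as.character(caseid_num)
  primaryid <- as.character(caseid_num * 10 + 1)

  ## --- drugs -------------------------------------------------------------
  present <- matrix(stats::runif(n * K), n, K) < rep(dc$p_use, each = n)
  none <- which(rowSums(present) == 0)
  if (length(none) > 0) {
    forced <- sample.int(K, length(none), replace = TRUE, prob = dc$p_use)
    present[cbind(none, forced)] <- TRUE
  }
  role_mat <- matrix(NA_character_, n, K)
  roles <- c("PS", "SS", "C", "I")
  for (k in seq_len(K)) {
    idx <- which(present[, k])
    if (length(idx) > 0) {
      role_mat[idx, k] <- sample(roles, length(idx), replace = TRUE,
                                 prob = c(dc$p_ps[k], dc$p_ss[k], dc$p_c[k], dc$p_i[k]))
    }
  }

  ## --- events ------------------------------------------------------------
  q <- matrix(rep(pc$p_event, each = n), n, P)
  if (nrow(config$signal_spec) > 0) {
    for (s in seq_len(nrow(config$signal_spec))) {
      di <- match(config$signal_spec$drug[s], dc$drug)
      pi <- match(config$signal_spec$pt[s], pc$pt)
      rows <- present[, di]
      q[rows, pi] <- pmin(1, pc$p_event[pi] * config$signal_spec$multiplier[s])
    }
  }
  has_event <- matrix(stats::runif(n * P), n, P) < q
  none_ev <- which(rowSums(has_event) == 0)
  if (length(none_ev) > 0) {
    forced_pt <- sample_weighted_rows(q[none_ev, , drop = FALSE])
    ok <- !is.na(forced_pt)
    has_event[cbind(none_ev[ok], forced_pt[ok])] <- TRUE
  }

  ## --- dates -------------------------------------------------------------
  window_days <- as.integer(config$date_window[2] - config$date_window[1])
  start_date <- config$date_window[1] +
    sample.int(window_days + 1L, n, replace = TRUE) - 1L
  onset_days <- pmax(0L, as.integer(round(
    stats::rlnorm(n, config$onset_meanlog, config$onset_sdlog))))
  event_date <- start_date + onset_days
  fda_date <- event_date + sample.int(61L, n, replace = TRUE) - 1L

  swap <- stats::runif(n) < config$negative_onset_rate
  tmp <- start_date[swap]
  start_date[swap] <- event_date[swap]
  event_date[swap] <- tmp

  start_dt <- date_to_faers(start_date)
  event_dt <- date_to_faers(event_date)
  fda_dt <- date_to_faers(fda_date)

  start_dt[stats::runif(n) < config$missing_start_rate] <- NA_character_
  event_dt[stats::runif(n) < config$missing_event_rate] <- NA_character_

  truncate_partial <- function(x, rate) {
    hit <- !is.na(x) & stats::runif(length(x)) < rate
    width <- ifelse(stats::runif(length(x)) < 0.5, 6L, 4L)
    x[hit] <- substr(x[hit], 1L, width[hit])
    x
  }
  start_dt <- truncate_partial(start_dt, config$partial_date_rate)
  event_dt <- truncate_partial(event_dt, config$partial_date_rate)

  ## --- demographics ------------------------------------------------------
  sex <- sample(c("F", "M", NA), n, replace = TRUE, prob = c(0.559, 0.329, 0.112))
  age <- rep(NA_real_, n)
  has_age <- stats::runif(n) >= 0.445
  n_age <- sum(has_age)
  age_band <- sample.int(3L, n_age, replace = TRUE, prob = c(0.34, 0.655, 0.005))
  age[has_age] <- dplyr::case_when(
    age_band == 1L ~ stats::runif(n_age, 12, 18),
    age_band == 2L ~ stats::runif(n_age, 18, 66),
    TRUE ~ stats::runif(n_age, 66, 86)
  )
  age <- floor(age)
  age_cod <- ifelse(is.na(age), NA_character_,
                    ifelse(stats::runif(n) < 0.02, "MON", "YR"))
  age <- ifelse(!is.na(age_cod) & age_cod == "MON", age * 12, age)
  occp_cod <- sample(c("MD", "CN", "OT", "LW", "HP", "PH", "RN", NA), n,
                     replace = TRUE,
                     prob = c(0.332, 0.297, 0.126, 0.111, 0.060, 0.020, 0.001, 0.053))
  country <- sample(c("US", "GB", "CA", "BR", "AU", "FR", "DE", NA), n,
                    replace = TRUE,
                    prob = c(0.811, 0.022, 0.009, 0.005, 0.005, 0.010, 0.010, 0.128))

  demo <- tibble(
    primaryid = primaryid, caseid = caseid, fda_dt = fda_dt,
    event_dt = event_dt, sex = sex, age = age, age_cod = age_cod,
    reporter_country = country, occp_cod = occp_cod
  )

  ## --- drug / ther / indi rows -------------------------------------------
  drug_idx <- which(present, arr.ind = TRUE)
  drug_idx <- drug_idx[order(drug_idx[, 1], drug_idx[, 2]), , drop = FALSE]
  case_of <- drug_idx[, 1]
  drug_of <- drug_idx[, 2]
  drug_seq <- stats::ave(case_of, case_of, FUN = seq_along)
  drug <- tibble(
    primaryid = primaryid[case_of], caseid = caseid[case_of],
    drug_seq = as.integer(drug_seq),
    role_cod = role_mat[cbind(case_of, drug_of)],
    drugname = dc$drug[drug_of],
    prod_ai = dc$drug[drug_of]
  )
  ther <- tibble(
    primaryid = primaryid[case_of], caseid = caseid[case_of],
    dsg_drug_seq = as.integer(drug_seq),
    start_dt = start_dt[case_of],
    end_dt = date_to_faers(start_date[case_of] +
                             sample.int(150L, length(case_of), replace = TRUE) + 29L)
  )
  has_indi <- stats::runif(length(case_of)) < 0.5
  indi <- tibble(
    primaryid = primaryid[case_of][has_indi],
    caseid = caseid[case_of][has_indi],
    indi_drug_seq = as.integer(drug_seq)[has_indi],
    indi_pt = sample(c("Acne", "Acne cystic", "Rosacea",
                       "Product used for unknown indication"),
                     sum(has_indi), replace = TRUE,
                     prob = c(0.55, 0.15, 0.05, 0.25))
  )

  ## --- reac rows ---------------------------------------------------------
  ev_idx <- which(has_event, arr.ind = TRUE)
  ev_idx <- ev_idx[order(ev_idx[, 1], ev_idx[, 2]), , drop = FALSE]
  reac <- tibble(
    primaryid = primaryid[ev_idx[, 1]], caseid = caseid[ev_idx[, 1]],
    pt = pc$pt[ev_idx[, 2]]
  )

  ## --- outc rows ---------------------------------------------------------
  outc_codes <- c("DE", "LT", "HO", "DS", "CA", "RI", "OT")
  outc_probs <- c(0.017, 0.010, 0.074, 0.012, 0.006, 0.002, 0.453)
  outc_mat <- matrix(stats::runif(n * 7L), n, 7L) < rep(outc_probs, each = n)
  oc_idx <- which(outc_mat, arr.ind = TRUE)
  oc_idx <- oc_idx[order(oc_idx[, 1], oc_idx[, 2]), , drop = FALSE]
  outc <- tibble(
    primaryid = primaryid[oc_idx[, 1]], caseid = caseid[oc_idx[, 1]],
    outc_cod = outc_codes[oc_idx[, 2]]
  )

  ## --- realized signal counts (pair-level, target = PS mentions) ---------
  signal_counts <- NULL
  if (nrow(config$signal_spec) > 0) {
    n_pairs_total <- sum(has_event)
    signal_counts <- purrr::pmap_dfr(config$signal_spec, function(drug, pt, multiplier) {
      di <- match(drug, dc$drug)
      pi <- match(pt, pc$pt)
      is_target <- present[, di] & !is.na(role_mat[, di]) & role_mat[, di] == "PS"
      a <- sum(has_event[is_target, pi])
      b <- sum(has_event[is_target, ]) - a
      cc <- sum(has_event[!is_target, pi])
      tibble(drug = drug, pt = pt, multiplier = multiplier,
             a = a, b = b, c = cc, d = n_pairs_total - a - b - cc)
    })
  }

  tables <- list(demo = demo, drug = drug, reac = reac, ther = ther,
                 outc = outc, indi = indi)
  dup <- inject_duplicates(tables, config$dup_rate, seed = config$seed + 1L)

  truth <- structure(
    list(signal_counts = signal_counts, dedup_ledger = dup$ledger,
         config = config),
    class = "sim_truth"
  )
  list(tables = dup$tables, truth = truth)
}

#' Inject duplicate case versions into a FAERS table set
#'
#' For each selected case, re-emits all of its rows under a new, strictly
#' larger PRIMARYID whose FDA_DT is at or after the original's (1-180 days
#' later; with probability 0.1 the same day, exercising the PRIMARYID
#' tie-break). Deduplication applied afterwards must recover exactly one
#' version per CASEID — the ledger records which.
#'
#' @param tables Named list of the six FAERS tibbles.
#' @param dup_rate Probability in `[0, 1]` that a case is duplicated.
#' @param seed Integer seed.
#' @return A list with `tables` (augmented) and `ledger`, a tibble with one
#'   row per DEMO version: `caseid`, `primaryid`, `fda_dt`, `is_duplicate`,
#'   `retain` (TRUE for the version deduplication must keep).
#' @export
inject_duplicates <- function(tables, dup_rate, seed = 1L) {
  if (length(dup_rate) != 1 || is.na(dup_rate) || dup_rate < 0 || dup_rate > 1) {
    stop("configuration error: 'dup_rate' must be a probability in [0, 1]",
         call. = FALSE)
  }
  set.seed(seed)
  demo <- tables$demo
  n <- nrow(demo)
  dup_sel <- stats::runif(n) < dup_rate
  idx <- which(dup_sel)

  if (length(idx) == 0) {
    ledger <- tibble(caseid = demo$caseid, primaryid = demo$primaryid,
                     fda_dt = demo$fda_dt, is_duplicate = FALSE, retain = TRUE)
    return(list(tables = tables, ledger = ledger))
  }

  old_pid <- demo$primaryid[idx]
  new_pid <- as.character(suppressWarnings(as.numeric(old_pid)) + 1)
  same_day <- stats::runif(length(idx)) < 0.1
  lag <- sample.int(180L, length(idx), replace = TRUE)
  old_date <- faers_date_parse(demo$fda_dt[idx])
  new_fda <- ifelse(same_day, demo$fda_dt[idx],
                    date_to_faers(old_date + lag))
  # a missing original FDA_DT stays missing on the copy
  new_fda[is.na(demo$fda_dt[idx])] <- NA_character_

  dup_demo <- demo[idx, ]
  dup_demo$primaryid <- new_pid
  dup_demo$fda_dt <- new_fda

  pid_map <- stats::setNames(new_pid, old_pid)
  copy_rows <- function(tbl) {
    cp <- tbl[tbl$primaryid %in% old_pid, , drop = FALSE]
    cp$primaryid <- unname(pid_map[cp$primaryid])
    dplyr::bind_rows(tbl, cp)
  }

  out <- list(
    demo = dplyr::bind_rows(demo, dup_demo),
    drug = copy_rows(tables$drug),
    reac = copy_rows(tables$reac),
    ther = copy_rows(tables$ther),
    outc = copy_rows(tables$outc),
    indi = copy_rows(tables$indi)
  )

  # ground truth of which version survives: the copy has FDA_DT >= the
  # original and a strictly larger PRIMARYID, so it always wins; except a
  # copy of a missing-FDA_DT original, which still wins on the PRIMARYID
  # tie (both sort as missing).
  ledger <- dplyr::bind_rows(
    tibble(caseid = demo$caseid, primaryid = demo$primaryid,
           fda_dt = demo$fda_dt, is_duplicate = FALSE,
           retain = !dup_sel),
    tibble(caseid = demo$caseid[idx], primaryid = new_pid,
           fda_dt = new_fda, is_duplicate = TRUE, retain = TRUE)
  )
  ledger <- dplyr::arrange(ledger, .data$caseid, .data$primaryid)
  list(tables = out, ledger = ledger)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("<sim_truth>\n  cases: ", x$config$n_cases,
      "\n  designed signal pairs: ",
      if (is.null(x$signal_counts)) 0 else nrow(x$signal_counts),
      "\n  duplicated cases: ", sum(x$dedup_ledger$is_duplicate), "\n", sep = "")
  invisible(x)
}
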