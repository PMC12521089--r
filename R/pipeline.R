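#' Configure the end-to-end analysis pipeline
#'
#' Collects everything [run_faers_pipeline()] needs: the six raw tables (in
#' memory or as a directory of "$"-delimited files), the lookup tables, the
#' target-drug synonym list and the analysis settings.
#'
#' @param tables Named list of the six tibbles (e.g. from
#'   [simulate_faers()]), or `NULL` to read from `input_dir`.
#' @param input_dir Directory with `demo.txt` ... `indi.txt` (see
#'   [read_faers_tables()]); ignored when `tables` is given.
#' @param lookups A [faers_lookups()] object.
#' @param synonyms Target-drug names; defaults to `lookups$synonyms`.
#' @param required_role Drug role the cohort requires (default `"PS"`).
#' @param match Drug-name matching mode (`"exact"` or `"substring"`).
#' @param criteria A [criteria_config()].
#' @param counting Contingency counting unit, `"pair"` or `"report"`.
#' @param level `"pt"`, `"soc"` or `"both"` (default).
#' @param tto_bins Upper day cutoffs for [summarize_tto()].
#' @param top_k Top-k for country/indication summaries.
#' @param out_dir Optional output directory; when given, every result table
#'   is written as CSV plus a `manifest.txt` of stage counts and settings.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(tables = NULL, input_dir = NULL, lookups,
                            synonyms = NULL, required_role = "PS",
                            match = "exact", criteria = criteria_config(),
                            counting = "pair", level = "both",
                            tto_bins = default_tto_bins(), top_k = 5,
                            out_dir = NULL) {
  if (is.null(tables) && is.null(input_dir)) {
    stop("configuration error: provide 'tables' or 'input_dir'", call. = FALSE)
  }
  if (!inherits(lookups, "faers_lookups")) {
    stop("configuration error: 'lookups' must be a faers_lookups object",
         call. = FALSE)
  }
  synonyms <- synonyms %||% lookups$synonyms
  if (length(synonyms) == 0) {
    stop("configuration error: no drug synonyms supplied (directly or via ",
         "lookups$synonyms)", call. = FALSE)
  }
  if (nrow(lookups$pt_to_soc) == 0) {
    stop("configuration error: the PT-to-SOC map is empty", call. = FALSE)
  }
  level <- match.arg(level, c("both", "pt", "soc"))
  counting <- match.arg(counting, c("pair", "report"))
  structure(
    list(tables = tables, input_dir = input_dir, lookups = lookups,
         synonyms = synonyms, required_role = required_role, match = match,
         criteria = criteria, counting = counting, level = level,
         tto_bins = tto_bins, top_k = top_k, out_dir = out_dir),
    class = "pipeline_config"
  )
}

#' Run the full signal-detection pipeline
#'
#' Executes every stage in order — read, deduplicate, select the drug
#' cohort, standardise terms, build contingency tables, compute the four
#' estimators and consensus flags at the requested MedDRA level(s), compute
#' time to onset and the demographic summary — and records row counts of
#' every stage in a manifest. Deterministic for fixed inputs.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `faers_pipeline_result` with elements `cases`
#'   (clean case tibble), `signals_pt`, `signals_soc` ([detect_signals()]
#'   tables, `NULL` for a level not requested), `signals_ime` (PT-level
#'   consensus signals restricted to IME terms), `tto` (per-case onset
#'   records), `tto_summary`, `demographics` and `manifest` (named character
#'   vector).
#' @export
run_faers_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  tables <- config$tables %||% read_faers_tables(config$input_dir)
  lookups <- config$lookups
  manifest <- c(
    n_demo_rows = nrow(tables$demo),
    n_raw_cases = dplyr::n_distinct(tables$demo$caseid)
  )

  retained <- dedup_reports(tables$demo)
  manifest["n_after_dedup"] <- length(retained)
  selected <- select_drug_reports(tables$drug, config$synonyms,
                                  required_role = config$required_role,
                                  match = config$match)
  manifest["n_drug_selected"] <- length(intersect(selected, retained))

  cases <- build_clean_cases(tables, lookups, retained, selected)
  manifest["n_clean_cases"] <- nrow(cases)
  if (nrow(cases) == 0) {
    warning("no clean cases after deduplication and drug selection; ",
            "emitting empty outputs", call. = FALSE)
  }

  # disproportionality universe: every retained report, flagged target or not
  universe <- suppressWarnings(standardize_events(
    tables$reac |> dplyr::filter(.data$primaryid %in% retained), lookups
  ))
  manifest["n_unmapped_pts"] <- attr(universe, "n_unmapped") %||% 0L
  universe <- universe |>
    dplyr::mutate(is_target = .data$primaryid %in% selected)
  manifest["n_event_pairs"] <- nrow(universe)

  signals_pt <- signals_soc <- signals_ime <- NULL
  if (config$level %in% c("both", "pt")) {
    signals_pt <- detect_signals(universe, level = "pt",
                                 counting = config$counting,
                                 criteria = config$criteria)
    pt_prior <- attr(signals_pt, "prior")
    term_flags <- universe |>
      dplyr::distinct(.data$pt, .data$is_ime, .data$is_unlabeled) |>
      dplyr::rename(term = "pt")
    signals_pt <- as_tibble(signals_pt) |>
      dplyr::left_join(term_flags, by = "term")
    signals_pt <- structure(
      signals_pt, class = c("faers_signals", class(signals_pt)),
      prior = pt_prior, criteria = config$criteria, level = "pt"
    )
    signals_ime <- signals_pt |>
      dplyr::filter(.data$is_ime, .data$consensus)
  }
  if (config$level %in% c("both", "soc")) {
    signals_soc <- detect_signals(universe, level = "soc",
                                  counting = config$counting,
                                  criteria = config$criteria)
  }
  manifest["n_pt_terms"] <- if (is.null(signals_pt)) NA else nrow(signals_pt)
  manifest["n_pt_consensus"] <- if (is.null(signals_pt)) NA else sum(signals_pt$consensus)
  manifest["n_ime_consensus"] <- if (is.null(signals_ime)) NA else nrow(signals_ime)

  tto <- compute_tto(cases, tables$drug, tables$ther, config$synonyms,
                     match = config$match)
  tto_summary <- summarize_tto(tto, bin_edges = config$tto_bins)
  manifest["n_tto_included"] <- tto_summary$n_included
  manifest["n_tto_missing_date"] <- tto_summary$n_missing_date
  manifest["n_tto_negative"] <- tto_summary$n_negative

  demographics <- summarize_demographics(cases, top_k = config$top_k)

  manifest <- c(
    manifest,
    counting = config$counting, level = config$level,
    required_role = config$required_role %||% "any",
    match = config$match,
    min_count = config$criteria$min_count, prr_min = config$criteria$prr_min,
    chi2_min = config$criteria$chi2_min, ic025_min = config$criteria$ic025_min,
    ebgm_min = config$criteria$ebgm_min, ebgm_stat = config$criteria$ebgm_stat
  )

  result <- structure(
    list(cases = cases, signals_pt = signals_pt, signals_soc = signals_soc,
         signals_ime = signals_ime, tto = tto, tto_summary = tto_summary,
         demographics = demographics, manifest = manifest),
    class = "faers_pipeline_result"
  )
  if (!is.null(config$out_dir)) write_pipeline_outputs(result, config$out_dir)
  result
}

flatten_cases_for_csv <- function(cases) {
  if (nrow(cases) == 0) {
    return(tibble(caseid = character(), primaryid = character(),
                  fda_dt = character(), event_dt = character(),
                  sex = character(), age_years = numeric(),
                  age_group = character(), reporter_class = character(),
                  country = character(), outcomes = character(),
                  indications = character(), pt = character(),
                  soc = character(), is_ime = logical(),
                  is_unlabeled = logical()))
  }
  cases |>
    dplyr::mutate(
      outcomes = purrr::map_chr(.data$outcomes, paste, collapse = ";"),
      indications = purrr::map_chr(.data$indications, paste, collapse = ";")
    ) |>
    tidyr::unnest("events", keep_empty = TRUE)
}

write_pipeline_outputs <- function(result, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  wr <- function(x, name) {
    if (!is.null(x)) readr::write_csv(x, file.path(out_dir, name))
  }
  wr(flatten_cases_for_csv(result$cases), "clean_cases.csv")
  wr(result$signals_pt, "signals_pt.csv")
  wr(result$signals_soc, "signals_soc.csv")
  wr(result$signals_ime, "signals_ime.csv")
  wr(result$tto, "tto_records.csv")
  wr(result$tto_summary$bins, "tto_bins.csv")
  wr(tibble(
    statistic = c("n_cases", "n_included", "n_missing_date", "n_negative",
                  "median_days", "q1", "q3"),
    value = c(result$tto_summary$n_cases, result$tto_summary$n_included,
              result$tto_summary$n_missing_date, result$tto_summary$n_negative,
              result$tto_summary$median_days, result$tto_summary$q1,
              result$tto_summary$q3)
  ), "tto_summary.csv")
  wr(result$demographics, "demographics.csv")
  writeLines(paste0(names(result$manifest), "=", unname(result$manifest)),
             file.path(out_dir, "manifest.txt"))
  invisible(out_dir)
}

#' @export
print.faers_pipeline_result <- function(x, ...) {
  cat("<faers_pipeline_result>\n")
  cat("  clean cases: ", nrow(x$cases), "\n", sep = "")
  if (!is.null(x$signals_pt)) {
    cat("  PT terms analysed: ", nrow(x$signals_pt),
        " (consensus: ", sum(x$signals_pt$consensus), ")\n", sep = "")
  }
  if (!is.null(x$signals_soc)) {
    cat("  SOC terms analysed: ", nrow(x$signals_soc),
        " (consensus: ", sum(x$signals_soc$consensus), ")\n", sep = "")
  }
  cat("  TTO included: ", x$tto_summary$n_included, "\n", sep = "")
  invisible(x)
}
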