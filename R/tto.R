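#' Compute time to adverse-event onset
#'
#' Onset is the calendar-day difference between the reported event date
#' (DEMO's event date, the FAERS field for adverse-event onset) and the
#' earliest therapy start date among the target drug's THER rows — first
#' exposure bounds onset when multiple therapy episodes exist. Day-resolution
#' arithmetic requires full, valid 8-digit dates on both sides; otherwise the
#' case is excluded as `missing_date`. Negative differences are excluded as
#' `negative`.
#'
#' @param cases Clean case tibble from [build_clean_cases()].
#' @param drug,ther DRUG and THER tibbles (for locating the target drug's
#'   therapy rows through `drug_seq`).
#' @param synonyms Target-drug name list, matched as in
#'   [select_drug_reports()].
#' @param required_role Optional role filter for the matching drug rows;
#'   `NULL` (default) accepts any role.
#' @param match Name matching mode, `"exact"` or `"substring"`.
#' @return Tibble with one row per case: `caseid`, `primaryid`,
#'   `onset_days` (integer, `NA` when excluded), `included`,
#'   `exclusion_reason` (`"none"`, `"missing_date"`, `"negative"`).
#' @export
compute_tto <- function(cases, drug, ther, synonyms, required_role = NULL,
                        match = "exact") {
  target_rows <- drug |>
    dplyr::filter(.data$primaryid %in% cases$primaryid)
  syn <- normalize_name(synonyms)
  is_target_row <- if (match == "exact") {
    normalize_name(target_rows$drugname) %in% syn |
      (!is.na(target_rows$prod_ai) & normalize_name(target_rows$prod_ai) %in% syn)
  } else {
    nm <- normalize_name(target_rows$drugname)
    ai <- normalize_name(target_rows$prod_ai)
    Reduce(`|`, lapply(syn, function(s) {
      grepl(s, nm, fixed = TRUE) | (!is.na(ai) & grepl(s, ai, fixed = TRUE))
    }))
  }
  if (!is.null(required_role)) {
    is_target_row <- is_target_row & !is.na(target_rows$role_cod) &
      target_rows$role_cod == required_role
  }
  seq_map <- target_rows[is_target_row, c("primaryid", "drug_seq")]

  starts <- ther |>
    dplyr::inner_join(seq_map,
                      by = c("primaryid", "dsg_drug_seq" = "drug_seq")) |>
    dplyr::mutate(start_date = faers_date_parse(.data$start_dt)) |>
    dplyr::filter(!is.na(.data$start_date))
  starts <- if (nrow(starts) == 0) {
    tibble(primaryid = character(), start_date = as.Date(character()))
  } else {
    dplyr::summarise(starts, start_date = min(.data$start_date),
                     .by = "primaryid")
  }

  cases |>
    dplyr::select("caseid", "primaryid", "event_dt") |>
    dplyr::left_join(starts, by = "primaryid") |>
    dplyr::mutate(
      event_date = faers_date_parse(.data$event_dt),
      onset_days = as.integer(.data$event_date - .data$start_date),
      exclusion_reason = dplyr::case_when(
        is.na(.data$onset_days) ~ "missing_date",
        .data$onset_days < 0 ~ "negative",
        .default = "none"
      ),
      included = .data$exclusion_reason == "none",
      onset_days = dplyr::if_else(.data$included, .data$onset_days, NA_integer_)
    ) |>
    dplyr::select("caseid", "primaryid", "onset_days", "included",
                  "exclusion_reason")
}

default_tto_bins <- function() c(30, 60, 90, 180, 360)

#' Summarise the time-to-onset distribution
#'
#' Median and interquartile range (linear-interpolation quantiles, the
#' inclusive method) plus counts and proportions over day bins. The default
#' bins — 0-30, 31-60, 61-90, 91-180, 181-360 and over 360 days — mirror the
#' monthly/quarterly groupings conventional for onset reporting. Proportions
#' are over included records only.
#'
#' @param records Onset tibble from [compute_tto()].
#' @param bin_edges Strictly increasing upper day cutoffs of the bins; a
#'   final open bin above the last cutoff is added automatically.
#' @return An object of class `tto_summary`: list with `n_cases`,
#'   `n_included`, `n_missing_date`, `n_negative`, `median_days`, `q1`, `q3`
#'   and `bins` (tibble `bin`, `lo`, `hi`, `count`, `proportion`).
#' @export
summarize_tto <- function(records, bin_edges = default_tto_bins()) {
  if (length(bin_edges) < 1 || is.unsorted(bin_edges, strictly = TRUE) ||
      any(bin_edges < 0)) {
    stop("configuration error: 'bin_edges' must be strictly increasing ",
         "non-negative day cutoffs", call. = FALSE)
  }
  days <- records$onset_days[records$included]
  k <- length(bin_edges)
  lo <- c(0, bin_edges + 1)
  hi <- c(bin_edges, Inf)
  labels <- c(paste0(lo[seq_len(k)], "-", bin_edges), paste0(">", bin_edges[k]))
  n_inc <- length(days)
  if (n_inc > 0) {
    counts <- as.integer(table(cut(days, breaks = c(-1, bin_edges, Inf),
                                   labels = labels)))
    qs <- stats::quantile(days, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  } else {
    counts <- rep(0L, length(labels))
    qs <- rep(NA_real_, 3)
  }
  structure(
    list(
      n_cases = nrow(records),
      n_included = n_inc,
      n_missing_date = sum(records$exclusion_reason == "missing_date"),
      n_negative = sum(records$exclusion_reason == "negative"),
      median_days = qs[2], q1 = qs[1], q3 = qs[3],
      bins = tibble(
        bin = labels, lo = lo, hi = hi, count = counts,
        proportion = if (n_inc > 0) counts / n_inc else rep(NA_real_, length(counts))
      ),
      empty = n_inc == 0
    ),
    class = "tto_summary"
  )
}

#' @export
print.tto_summary <- function(x, ...) {
  cat("<tto_summary> included=", x$n_included, "/", x$n_cases,
      " (missing_date=", x$n_missing_date, ", negative=", x$n_negative, ")\n",
      sep = "")
  if (!x$empty) {
    cat(sprintf("  median %s days (IQR %s-%s)\n", format(x$median_days),
                format(x$q1), format(x$q3)))
  }
  print(x$bins)
  invisible(x)
}
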