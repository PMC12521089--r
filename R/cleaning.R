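#' Deduplicate spontaneous reports
#'
#' FAERS publishes successive versions of the same case under new
#' PRIMARYIDs. Following the standard cleaning rule, records are grouped by
#' CASEID and the most recent version is kept: the maximum FDA_DT, and among
#' versions sharing that FDA_DT, the maximum PRIMARYID. A version with a
#' missing (or partial, hence day-unusable) FDA_DT sorts before any dated
#' version, so a dated version always supersedes it.
#'
#' @param demo Tibble of DEMO records (`primaryid`, `caseid`, `fda_dt`).
#' @return Character vector of retained PRIMARYIDs, one per distinct CASEID.
#' @examples
#' demo <- tibble::tibble(
#'   primaryid = c("1", "2"), caseid = c("100", "100"),
#'   fda_dt = c("20200101", "20200301")
#' )
#' dedup_reports(demo)
#' @export
dedup_reports <- function(demo) {
  if (nrow(demo) == 0) return(character())
  pid_num <- suppressWarnings(as.numeric(demo$primaryid))
  # PRIMARYIDs are numeric strings in FAERS; fall back to lexical order if not
  pid_rank <- if (anyNA(pid_num)) rank(demo$primaryid, ties.method = "first") else pid_num
  d <- tibble(
    caseid = demo$caseid,
    primaryid = demo$primaryid,
    date = faers_date_parse(demo$fda_dt),
    pid_rank = pid_rank
  )
  d |>
    dplyr::group_by(.data$caseid) |>
    dplyr::arrange(
      dplyr::desc(!is.na(.data$date)), dplyr::desc(.data$date),
      dplyr::desc(.data$pid_rank), .by_group = TRUE
    ) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::pull(.data$primaryid)
}

normalize_name <- function(x) toupper(trimws(x))

#' Select reports mentioning the target drug in a given role
#'
#' A report is selected iff at least one of its DRUG rows matches a synonym
#' (after uppercasing and trimming, exact match by default against `drugname`
#' or `prod_ai`) *and* carries the required role code. The default role is
#' `"PS"` (primary suspect): reports listing the drug only as secondary
#' suspect, concomitant or interacting are excluded to limit confounding.
#'
#' @param drug Tibble of DRUG records.
#' @param synonyms Character vector of trade/generic names (non-empty).
#' @param required_role Role code a matching row must carry; `NULL` accepts
#'   any role.
#' @param match Either `"exact"` (default) or `"substring"`. Substring
#'   matching is high-recall/low-precision on FAERS free-text drug names and
#'   is therefore opt-in.
#' @param search_prod_ai Also match the active-ingredient field (default
#'   TRUE).
#' @return Character vector of selected PRIMARYIDs.
#' @export
select_drug_reports <- function(drug, synonyms, required_role = "PS",
                                match = c("exact", "substring"),
                                search_prod_ai = TRUE) {
  match <- match.arg(match)
  synonyms <- normalize_name(synonyms)
  synonyms <- synonyms[!is.na(synonyms) & synonyms != ""]
  if (length(synonyms) == 0) {
    stop("configuration error: the drug synonym list is empty", call. = FALSE)
  }
  if (nrow(drug) == 0) return(character())

  name1 <- normalize_name(drug$drugname)
  name2 <- if (search_prod_ai && "prod_ai" %in% names(drug)) {
    normalize_name(drug$prod_ai)
  } else {
    rep(NA_character_, nrow(drug))
  }
  if (match == "exact") {
    hit <- (name1 %in% synonyms) | (!is.na(name2) & name2 %in% synonyms)
  } else {
    hit_one <- function(x) {
      out <- rep(FALSE, length(x))
      keep <- !is.na(x)
      for (s in synonyms) out[keep] <- out[keep] | grepl(s, x[keep], fixed = TRUE)
      out
    }
    hit <- hit_one(name1) | hit_one(name2)
  }
  if (!is.null(required_role)) {
    hit <- hit & !is.na(drug$role_cod) & drug$role_cod == required_role
  }
  unique(drug$primaryid[hit])
}

#' Standardise reaction terms and flag IME / unlabeled events
#'
#' Normalises Preferred Term strings (case-folded, trimmed), maps each to its
#' System Organ Class via the user-supplied PT-to-SOC map, and flags terms on
#' the Important Medical Event list and terms absent from the drug label.
#' PTs missing from the map are assigned the SOC `"UNMAPPED"` and counted in
#' a warning; the map is treated as authoritative and no reclassification is
#' performed.
#'
#' @param reac Tibble of REAC records (`primaryid`, `pt`).
#' @param lookups A [faers_lookups()] object with a non-empty `pt_to_soc`.
#' @return Tibble with one row per distinct (report, PT): `primaryid`, `pt`
#'   (original casing from the map where available), `soc`, `is_ime`,
#'   `is_unlabeled`.
#' @export
standardize_events <- function(reac, lookups) {
  stopifnot(inherits(lookups, "faers_lookups"))
  if (nrow(lookups$pt_to_soc) == 0) {
    stop("configuration error: the PT-to-SOC map is empty", call. = FALSE)
  }
  map <- lookups$pt_to_soc |>
    dplyr::mutate(pt_key = normalize_name(.data$pt)) |>
    dplyr::distinct(.data$pt_key, .keep_all = TRUE)
  ime_keys <- normalize_name(lookups$ime)
  label_keys <- normalize_name(lookups$label)

  ev <- tibble(primaryid = reac$primaryid, pt_key = normalize_name(reac$pt),
               pt_raw = trimws(reac$pt)) |>
    dplyr::filter(!is.na(.data$pt_key) & .data$pt_key != "") |>
    dplyr::distinct(.data$primaryid, .data$pt_key, .keep_all = TRUE) |>
    dplyr::left_join(map, by = "pt_key")

  n_unmapped <- sum(is.na(ev$soc))
  if (n_unmapped > 0) {
    warning(n_unmapped, " event(s) with PTs absent from the PT-to-SOC map ",
            "assigned SOC 'UNMAPPED'", call. = FALSE)
  }
  out <- ev |>
    dplyr::transmute(
      primaryid = .data$primaryid,
      pt = dplyr::coalesce(.data$pt, .data$pt_raw),
      soc = dplyr::if_else(is.na(.data$soc), "UNMAPPED", .data$soc),
      is_ime = .data$pt_key %in% ime_keys,
      is_unlabeled = !.data$pt_key %in% label_keys
    )
  attr(out, "n_unmapped") <- n_unmapped
  out
}

#' Normalise age to years
#'
#' FAERS ages come with a unit code: decades, years, months, weeks, days or
#' hours. Conversion uses the mean tropical-year constants (52.1775 weeks,
#' 365.25 days, 8766 hours per year).
#'
#' @param age Numeric age values.
#' @param age_cod Unit codes (`DEC`, `YR`, `MON`, `WK`, `DY`, `HR`); missing
#'   codes are treated as years.
#' @return Numeric vector of ages in years.
#' @export
age_in_years <- function(age, age_cod) {
  factor <- dplyr::case_when(
    is.na(age_cod) | age_cod == "YR" ~ 1,
    age_cod == "DEC" ~ 10,
    age_cod == "MON" ~ 1 / 12,
    age_cod == "WK" ~ 1 / 52.1775,
    age_cod == "DY" ~ 1 / 365.25,
    age_cod == "HR" ~ 1 / 8766,
    .default = NA_real_
  )
  out <- age * factor
  out[!is.na(out) & out < 0] <- NA_real_
  out
}

age_group_levels <- c("<18", "18-65", "66-85", ">85", "missing")

# Half-open lower bins so that age exactly 18 falls in 18-65 and 66 in 66-85.
age_group_of <- function(age_years) {
  dplyr::case_when(
    is.na(age_years) ~ "missing",
    age_years < 18 ~ "<18",
    age_years < 66 ~ "18-65",
    age_years <= 85 ~ "66-85",
    .default = ">85"
  )
}

reporter_class_map <- c(
  MD = "Physician", CN = "Consumer", LW = "Lawyer",
  HP = "Health professional", OT = "Other health-professional",
  PH = "Pharmacist", RN = "Registered Nurse"
)

#' Assemble the deduplicated, drug-specific clean case set
#'
#' Intersects the deduplicated report set with the drug-selected report set
#' and assembles one row per case: normalised demographics (age in years and
#' age group, reporter class from the occupation code), outcomes, indications
#' and the standardised event list with SOC/IME/label flags as nested
#' tibbles.
#'
#' @param tables Named list of the six FAERS tibbles.
#' @param lookups A [faers_lookups()] object.
#' @param retained_ids PRIMARYIDs surviving [dedup_reports()].
#' @param selected_ids PRIMARYIDs from [select_drug_reports()].
#' @return A tibble with one row per case: `caseid`, `primaryid`, `fda_dt`,
#'   `event_dt`, `sex`, `age_years`, `age_group`, `reporter_class`,
#'   `country`, `outcomes` (list of codes), `indications` (list),
#'   `events` (list of tibbles `pt`, `soc`, `is_ime`, `is_unlabeled`).
#' @export
build_clean_cases <- function(tables, lookups, retained_ids, selected_ids) {
  ids <- intersect(retained_ids, selected_ids)
  demo <- tables$demo |> dplyr::filter(.data$primaryid %in% ids)
  if (nrow(demo) == 0) {
    return(tibble(
      caseid = character(), primaryid = character(), fda_dt = character(),
      event_dt = character(), sex = character(), age_years = numeric(),
      age_group = character(), reporter_class = character(),
      country = character(), outcomes = list(), indications = list(),
      events = list()
    ))
  }
  events <- standardize_events(
    tables$reac |> dplyr::filter(.data$primaryid %in% ids), lookups
  )
  ev_nest <- events |> tidyr::nest(events = -"primaryid")
  outc_nest <- tables$outc |>
    dplyr::filter(.data$primaryid %in% ids) |>
    dplyr::distinct(.data$primaryid, .data$outc_cod) |>
    dplyr::summarise(outcomes = list(.data$outc_cod), .by = "primaryid")
  indi_nest <- tables$indi |>
    dplyr::filter(.data$primaryid %in% ids, !is.na(.data$indi_pt)) |>
    dplyr::summarise(indications = list(unique(.data$indi_pt)), .by = "primaryid")

  demo |>
    dplyr::mutate(
      age_years = age_in_years(.data$age, .data$age_cod),
      age_group = age_group_of(.data$age_years),
      reporter_class = dplyr::if_else(
        is.na(.data$occp_cod), "Missing",
        unname(reporter_class_map[.data$occp_cod])
      ),
      reporter_class = dplyr::coalesce(.data$reporter_class, "Missing"),
      country = .data$reporter_country
    ) |>
    dplyr::left_join(ev_nest, by = "primaryid") |>
    dplyr::left_join(outc_nest, by = "primaryid") |>
    dplyr::left_join(indi_nest, by = "primaryid") |>
    dplyr::mutate(
      events = purrr::map(.data$events, ~ .x %||% tibble(
        pt = character(), soc = character(),
        is_ime = logical(), is_unlabeled = logical()
      )),
      outcomes = purrr::map(.data$outcomes, ~ .x %||% character()),
      indications = purrr::map(.data$indications, ~ .x %||% character())
    ) |>
    dplyr::select(
      "caseid", "primaryid", "fda_dt", "event_dt", "sex", "age_years",
      "age_group", "reporter_class", "country", "outcomes", "indications",
      "events"
    ) |>
    dplyr::arrange(.data$caseid)
}

#' Flatten clean cases to one row per case-event pair
#'
#' @param cases Tibble from [build_clean_cases()].
#' @return Tibble with the case columns repeated per event row.
#' @export
case_events <- function(cases) {
  cases |>
    dplyr::select(-"outcomes", -"indications") |>
    tidyr::unnest("events")
}
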