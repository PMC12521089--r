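outcome_labels <- c(
  DE = "Death", LT = "Life-Threatening", HO = "Hospitalization",
  DS = "Disability", CA = "Congenital Anomaly",
  RI = "Required Intervention to Prevent Permanent Impairment/Damage",
  OT = "Other Serious"
)

#' Summarise clinical characteristics of the clean case set
#'
#' Counts and percentages — denominator is the full case set, percentages
#' rounded to one decimal — for sex, age group, reporter class, the top-k
#' reporting countries, clinical outcomes (a case contributes to every
#' outcome it reports; cases with no outcome row count as Missing) and the
#' top-k indications, plus reports per year keyed on the FDA receipt year
#' (partial dates still contribute their year).
#'
#' @param cases Clean case tibble from [build_clean_cases()].
#' @param top_k How many countries / indications to list (default 5).
#' @return A tibble with columns `characteristic`, `level`, `n`, `pct`
#'   (`pct` is `NA` when the case set is empty).
#' @export
summarize_demographics <- function(cases, top_k = 5) {
  n_cases <- nrow(cases)
  pct_of <- function(n) if (n_cases > 0) round(100 * n / n_cases, 1) else NA_real_

  count_block <- function(characteristic, values, levels = NULL) {
    values <- ifelse(is.na(values), "Missing", values)
    tab <- table(values)
    lv <- levels %||% names(sort(tab, decreasing = TRUE))
    n <- as.integer(tab[lv])
    n[is.na(n)] <- 0L
    tibble(characteristic = characteristic, level = lv, n = n, pct = pct_of(n))
  }

  sex_block <- count_block("sex", cases$sex, levels = c("F", "M", "Missing"))
  age_block <- count_block(
    "age_group",
    dplyr::if_else(cases$age_group == "missing", "Missing", cases$age_group),
    levels = c("<18", "18-65", "66-85", ">85", "Missing")
  )
  rep_block <- count_block("reporter", cases$reporter_class)

  country_tab <- sort(table(cases$country[!is.na(cases$country)]),
                      decreasing = TRUE)
  country_block <- tibble(
    characteristic = "country",
    level = names(utils::head(country_tab, top_k)),
    n = as.integer(utils::head(country_tab, top_k)),
    pct = pct_of(as.integer(utils::head(country_tab, top_k)))
  )

  outc_flat <- unlist(cases$outcomes, use.names = FALSE)
  outc_tab <- table(factor(outc_flat, levels = names(outcome_labels)))
  n_no_outcome <- if (n_cases > 0) {
    sum(vapply(cases$outcomes, length, integer(1)) == 0)
  } else 0L
  outcome_block <- tibble(
    characteristic = "outcome",
    level = c(unname(outcome_labels), "Missing"),
    n = c(as.integer(outc_tab), n_no_outcome),
    pct = pct_of(c(as.integer(outc_tab), n_no_outcome))
  )

  indi_flat <- unlist(cases$indications, use.names = FALSE)
  indi_tab <- sort(table(indi_flat), decreasing = TRUE)
  indi_block <- tibble(
    characteristic = "indication",
    level = names(utils::head(indi_tab, top_k)),
    n = as.integer(utils::head(indi_tab, top_k)),
    pct = pct_of(as.integer(utils::head(indi_tab, top_k)))
  )

  years <- faers_date_year(cases$fda_dt)
  year_tab <- table(years)
  year_block <- tibble(
    characteristic = "year",
    level = names(year_tab),
    n = as.integer(year_tab),
    pct = pct_of(as.integer(year_tab))
  )

  dplyr::bind_rows(sex_block, age_block, rep_block, country_block,
                   outcome_block, indi_block, year_block)
}
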