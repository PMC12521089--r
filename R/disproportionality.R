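#' Build 2x2 contingency tables at the PT or SOC level
#'
#' Disproportionality compares how often a term is reported with the target
#' drug against how often it is reported with every other drug. The counting
#' unit is the distinct (report, term) pair: a report listing the same PT
#' twice contributes one pair, and a report with three distinct PTs
#' contributes three pairs. With `N` the total number of pairs at the chosen
#' MedDRA level,
#' \itemize{
#'   \item `a` = distinct target-drug reports mentioning the term,
#'   \item `b` = remaining target-drug pairs (other terms),
#'   \item `c` = distinct other-drug reports mentioning the term,
#'   \item `d` = `N - a - b - c`.
#' }
#' Margins then equal total term mentions, the standard convention for
#' spontaneous-report databases. `counting = "report"` switches to
#' report-level counting, where `N` is the number of reports and `b`, `c`,
#' `d` count reports without/with the term.
#'
#' Terms never co-occurring with the target drug (`a = 0`) are suppressed:
#' no disproportionality statistic is defined for them.
#'
#' @param events Tibble with one row per (report, term) event:
#'   columns `primaryid`, a term column (`pt` or `soc`), and logical
#'   `is_target`.
#' @param level `"pt"` or `"soc"`: which column names the term.
#' @param counting `"pair"` (default) or `"report"`.
#' @return Tibble with columns `term`, `level`, `a`, `b`, `c`, `d`, `n_total`,
#'   one row per term with `a >= 1`.
#' @export
build_contingency <- function(events, level = c("pt", "soc"),
                              counting = c("pair", "report")) {
  level <- match.arg(level)
  counting <- match.arg(counting)
  term_col <- level
  if (!term_col %in% names(events)) {
    stop("events has no '", term_col, "' column", call. = FALSE)
  }
  if (!"is_target" %in% names(events)) {
    stop("events must carry a logical 'is_target' column", call. = FALSE)
  }
  ev <- events |>
    dplyr::filter(!is.na(.data[[term_col]])) |>
    dplyr::distinct(.data$primaryid, term = .data[[term_col]], .data$is_target)
  if (nrow(ev) == 0) {
    return(tibble(term = character(), level = character(), a = integer(),
                  b = integer(), c = integer(), d = integer(),
                  n_total = integer()))
  }

  if (counting == "pair") {
    n_total <- nrow(ev)
    target_pairs <- sum(ev$is_target)
    counts <- ev |>
      dplyr::summarise(
        a = sum(.data$is_target), ac = dplyr::n(), .by = "term"
      ) |>
      dplyr::mutate(
        b = target_pairs - .data$a,
        c = .data$ac - .data$a,
        d = n_total - target_pairs - .data$c
      )
  } else {
    reports <- ev |> dplyr::distinct(.data$primaryid, .data$is_target)
    n_total <- nrow(reports)
    n_target <- sum(reports$is_target)
    counts <- ev |>
      dplyr::summarise(
        a = sum(.data$is_target), ac = dplyr::n(), .by = "term"
      ) |>
      dplyr::mutate(
        b = n_target - .data$a,
        c = .data$ac - .data$a,
        d = n_total - n_target - .data$c
      )
  }
  counts |>
    dplyr::filter(.data$a >= 1) |>
    dplyr::transmute(
      term = .data$term, level = toupper(level),
      a = as.integer(.data$a), b = as.integer(.data$b),
      c = as.integer(.data$c), d = as.integer(.data$d),
      n_total = as.integer(n_total)
    ) |>
    dplyr::arrange(.data$term)
}

# Haldane-Anscombe: add 0.5 to all four cells iff any of b, c, d is zero
# (a = 0 tables are never emitted), keeping the odds ratio finite without
# perturbing typical tables.
haldane_correct <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  zero <- b == 0 | c == 0 | d == 0
  k <- ifelse(zero, 0.5, 0)
  list(a = a + k, b = b + k, c = c + k, d = d + k, corrected = zero)
}

#' Reporting odds ratio with Wald confidence interval
#'
#' `ROR = (a d)/(b c)` with `exp(log ROR +/- z * se)`,
#' `se = sqrt(1/a + 1/b + 1/c + 1/d)`. Cells are Haldane-corrected (+0.5
#' everywhere) when any of `b`, `c`, `d` is zero.
#'
#' @param a,b,c,d Vectors of 2x2 cell counts (`a >= 1`).
#' @param z Normal quantile for the interval (1.96 for 95%).
#' @return Tibble with columns `ror`, `ror_lo`, `ror_hi`.
#' @examples
#' compute_ror(3, 7, 97, 893)
#' @export
compute_ror <- function(a, b, c, d, z = stats::qnorm(0.975)) {
  h <- haldane_correct(a, b, c, d)
  ror <- (h$a * h$d) / (h$b * h$c)
  se <- sqrt(1 / h$a + 1 / h$b + 1 / h$c + 1 / h$d)
  tibble(
    ror = ror,
    ror_lo = exp(log(ror) - z * se),
    ror_hi = exp(log(ror) + z * se)
  )
}

#' Proportional reporting ratio and Pearson chi-squared
#'
#' `PRR = [a/(a+b)] / [c/(c+d)]`; the chi-squared statistic is Pearson's
#' `N (ad - bc)^2 / [(a+b)(c+d)(a+c)(b+d)]`, without continuity correction by
#' default (`yates = TRUE` subtracts `N/2` from `|ad - bc|`). A zero margin
#' leaves both statistics missing.
#'
#' @inheritParams compute_ror
#' @param yates Apply the Yates continuity correction to chi-squared.
#' @return Tibble with columns `prr`, `chi2`.
#' @examples
#' compute_prr(3, 7, 97, 893)
#' @export
compute_prr <- function(a, b, c, d, yates = FALSE) {
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  m1 <- a + b; m2 <- c + d; m3 <- a + c; m4 <- b + d
  bad <- m1 == 0 | m2 == 0 | m3 == 0 | m4 == 0
  prr <- ifelse(bad, NA_real_, (a / m1) / (c / m2))
  dev <- abs(a * d - b * c)
  if (yates) dev <- pmax(0, dev - n / 2)
  chi2 <- ifelse(bad, NA_real_, n * dev^2 / (m1 * m2 * m3 * m4))
  tibble(prr = prr, chi2 = chi2)
}

#' BCPNN information component with closed-form credibility bound
#'
#' The information component is the posterior log2 ratio of the joint
#' reporting probability of (drug, term) to the product of its margins,
#' under the standard closed-form Bayesian confidence propagation
#' formulation with Beta(1, 1) margins, a Beta(2, 2)-anchored joint, and the
#' adaptive joint prior count
#' `gamma = (N + 2)^2 / ((a+b+1)(a+c+1))` (at the default constants). The
#' lower credibility bound is the normal approximation
#' `ic025 = ic - z * sqrt(v)` with the delta-method posterior variance `v`;
#' `z = 1.96` by default, with `z = 2` available as the classical variant.
#'
#' @inheritParams compute_ror
#' @param z Quantile multiplier for the lower bound (1.96 default; 2 for the
#'   classical variant).
#' @return Tibble with columns `ic`, `ic025` (bits).
#' @export
compute_bcpnn <- function(a, b, c, d, z = stats::qnorm(0.975)) {
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  g11 <- 1; a1 <- 1; b1 <- 1; alpha <- 2; beta <- 2
  gamma <- g11 * (n + alpha) * (n + beta) / ((a + b + a1) * (a + c + b1))
  ic <- log2((a + g11) * (n + alpha) * (n + beta) /
               ((n + gamma) * (a + b + a1) * (a + c + b1)))
  v <- (1 / log(2)^2) * (
    (n - a + gamma - g11) / ((a + g11) * (1 + n + gamma)) +
    (n - a - b + alpha - a1) / ((a + b + a1) * (1 + n + alpha)) +
    (n - a - c + beta - b1) / ((a + c + b1) * (1 + n + beta))
  )
  tibble(ic = ic, ic025 = ic - z * sqrt(v))
}

#' Signal-significance thresholds
#'
#' The per-estimator significance criteria: at least `min_count` reports and
#' an ROR 95% CI lower bound above 1; `PRR >= 2` with `chi2 >= 4` and at
#' least `min_count` reports; `IC025 > 0`; and `EBGM >= 2` (or the more
#' conservative `EBGM05 >= 2` when `ebgm_stat = "EBGM05"`). A term is a
#' consensus signal only when all four hold.
#'
#' @param min_count Minimum report count `a` (default 3).
#' @param prr_min,chi2_min PRR and chi-squared thresholds (2 and 4).
#' @param ic025_min IC lower-bound threshold (0, strict inequality).
#' @param ebgm_min EBGM threshold (2).
#' @param ebgm_stat Which empirical-Bayes statistic is gated: `"EBGM"`
#'   (default) or `"EBGM05"`.
#' @param ci_z Normal quantile used for the ROR interval and the IC bound.
#' @return An object of class `criteria_config`.
#' @export
criteria_config <- function(min_count = 3, prr_min = 2, chi2_min = 4,
                            ic025_min = 0, ebgm_min = 2,
                            ebgm_stat = c("EBGM", "EBGM05"),
                            ci_z = stats::qnorm(0.975)) {
  ebgm_stat <- match.arg(ebgm_stat)
  vals <- c(min_count, prr_min, chi2_min, ic025_min, ebgm_min, ci_z)
  if (any(!is.finite(vals))) {
    stop("configuration error: all thresholds must be finite", call. = FALSE)
  }
  structure(
    list(min_count = min_count, prr_min = prr_min, chi2_min = chi2_min,
         ic025_min = ic025_min, ebgm_min = ebgm_min, ebgm_stat = ebgm_stat,
         ci_z = ci_z),
    class = "criteria_config"
  )
}

#' Apply the four-estimator significance criteria
#'
#' Sets the per-estimator flags and the consensus flag on a signal table.
#' A missing statistic fails its flag.
#'
#' @param stats_tbl Tibble with columns `n`, `ror_lo`, `prr`, `chi2`,
#'   `ic025`, `ebgm`, `ebgm05` (as produced by [detect_signals()]).
#' @param criteria A [criteria_config()].
#' @return `stats_tbl` with logical columns `ror_sig`, `prr_sig`,
#'   `bcpnn_sig`, `ebgm_sig`, `consensus` added (or replaced).
#' @export
apply_criteria <- function(stats_tbl, criteria = criteria_config()) {
  stopifnot(inherits(criteria, "criteria_config"))
  flag <- function(x) !is.na(x) & x
  eb <- if (criteria$ebgm_stat == "EBGM") stats_tbl$ebgm else stats_tbl$ebgm05
  out <- stats_tbl |>
    dplyr::mutate(
      ror_sig = flag(.data$n >= criteria$min_count & .data$ror_lo > 1),
      prr_sig = flag(.data$prr >= criteria$prr_min &
                       .data$chi2 >= criteria$chi2_min &
                       .data$n >= criteria$min_count),
      bcpnn_sig = flag(.data$ic025 > criteria$ic025_min),
      ebgm_sig = flag(eb >= criteria$ebgm_min),
      consensus = .data$ror_sig & .data$prr_sig & .data$bcpnn_sig & .data$ebgm_sig
    )
  out
}

#' Run the full disproportionality analysis at one MedDRA level
#'
#' Builds the contingency tables, computes all four estimators (fitting the
#' empirical-Bayes mixture prior across all tables at this level), and
#' applies the consensus criteria.
#'
#' @inheritParams build_contingency
#' @param criteria A [criteria_config()].
#' @param prior Optionally a pre-fitted [fit_mgps_prior()] result; fitted
#'   from the tables at this level when `NULL`.
#' @param bcpnn_z Quantile for the IC lower bound.
#' @return A tibble of class `faers_signals`, one row per term: the counts,
#'   the four estimators with uncertainty bounds, the per-estimator flags and
#'   `consensus`. The fitted prior, level and criteria are attached as
#'   attributes.
#' @export
detect_signals <- function(events, level = c("pt", "soc"),
                           counting = c("pair", "report"),
                           criteria = criteria_config(), prior = NULL,
                           bcpnn_z = stats::qnorm(0.975)) {
  level <- match.arg(level)
  counting <- match.arg(counting)
  ct <- build_contingency(events, level = level, counting = counting)
  if (nrow(ct) == 0) {
    out <- tibble(
      term = character(), level = character(), n = integer(), a = integer(),
      b = integer(), c = integer(), d = integer(), expected = numeric(),
      ror = numeric(), ror_lo = numeric(), ror_hi = numeric(),
      prr = numeric(), chi2 = numeric(), ic = numeric(), ic025 = numeric(),
      ebgm = numeric(), ebgm05 = numeric(), ror_sig = logical(),
      prr_sig = logical(), bcpnn_sig = logical(), ebgm_sig = logical(),
      consensus = logical()
    )
    return(structure(out, class = c("faers_signals", class(out)),
                     prior = prior, criteria = criteria, level = level))
  }
  expected <- (ct$a + ct$b) * (ct$a + ct$c) / ct$n_total
  if (is.null(prior)) {
    prior <- fit_mgps_prior(ct$a, expected)
  }
  eb <- compute_ebgm(ct$a, expected, prior)
  stats_tbl <- dplyr::bind_cols(
    ct |> dplyr::mutate(n = .data$a, expected = expected),
    compute_ror(ct$a, ct$b, ct$c, ct$d, z = criteria$ci_z),
    compute_prr(ct$a, ct$b, ct$c, ct$d),
    compute_bcpnn(ct$a, ct$b, ct$c, ct$d, z = bcpnn_z),
    eb
  ) |>
    dplyr::relocate("n", .after = "level")
  out <- apply_criteria(stats_tbl, criteria)
  structure(out, class = c("faers_signals", class(out)),
            prior = prior, criteria = criteria, level = level)
}

#' @export
print.faers_signals <- function(x, ...) {
  cat("<faers_signals> level=", attr(x, "level"),
      "  terms=", nrow(x),
      "  consensus signals=", sum(x$consensus), "\n", sep = "")
  NextMethod()
}
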