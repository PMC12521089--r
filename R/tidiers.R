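#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a fitted MGPS mixture prior
#'
#' @param x An `mgps_prior` from [fit_mgps_prior()].
#' @param ... Unused.
#' @return One row per hyperparameter: `term`, `estimate`.
#' @method tidy mgps_prior
#' @export
tidy.mgps_prior <- function(x, ...) {
  tibble(
    term = c("alpha1", "beta1", "alpha2", "beta2", "p_mix"),
    estimate = c(x$alpha1, x$beta1, x$alpha2, x$beta2, x$p_mix)
  )
}

#' @rdname tidy.mgps_prior
#' @return `glance()`: a one-row tibble with `loglik`, `converged`,
#'   `n_tables`.
#' @method glance mgps_prior
#' @export
glance.mgps_prior <- function(x, ...) {
  tibble(loglik = x$loglik, converged = x$converged, n_tables = x$n_tables)
}

#' Tidy a signal table
#'
#' Returns the signal table as a plain tibble in the conventional column
#' layout (term, SOC context where present, count, the four estimators with
#' their uncertainty bounds, and the flags).
#'
#' @param x A `faers_signals` table from [detect_signals()].
#' @param ... Unused.
#' @method tidy faers_signals
#' @export
tidy.faers_signals <- function(x, ...) {
  as_tibble(x)
}

#' @rdname tidy.faers_signals
#' @return `glance()`: one row with `level`, `n_terms`, `n_consensus` and
#'   the fitted prior's hyperparameters.
#' @method glance faers_signals
#' @export
glance.faers_signals <- function(x, ...) {
  prior <- attr(x, "prior")
  tibble(
    level = attr(x, "level"), n_terms = nrow(x),
    n_consensus = sum(x$consensus),
    alpha1 = prior$alpha1 %||% NA_real_, beta1 = prior$beta1 %||% NA_real_,
    alpha2 = prior$alpha2 %||% NA_real_, beta2 = prior$beta2 %||% NA_real_,
    p_mix = prior$p_mix %||% NA_real_
  )
}

#' @method tidy tto_summary
#' @export
tidy.tto_summary <- function(x, ...) {
  x$bins
}

#' @method glance tto_summary
#' @export
glance.tto_summary <- function(x, ...) {
  tibble(
    n_cases = x$n_cases, n_included = x$n_included,
    n_missing_date = x$n_missing_date, n_negative = x$n_negative,
    median_days = x$median_days, q1 = x$q1, q3 = x$q3
  )
}
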