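# shared fixtures and independent oracles

tiny_lookups <- function() {
  faers_lookups(
    pt_to_soc = default_pt_catalog()[, c("pt", "soc")],
    ime = c("Inflammatory bowel disease", "Suicidal ideation", "Depression"),
    label = c("Lip dry", "Cheilitis", "Dry skin", "Inflammatory bowel disease"),
    synonyms = c("ISOTRETINOIN", "ACCUTANE")
  )
}

signal_cfg <- function(n_cases, multiplier, seed,
                       pt = "Inflammatory bowel disease", ...) {
  sim_config(
    n_cases = n_cases, seed = seed,
    signal_spec = tibble::tibble(drug = "ISOTRETINOIN", pt = pt,
                                 multiplier = multiplier),
    ...
  )
}

# Brute-force disproportionality: enumerate distinct (report, term) pairs
# with base R only and compute ROR / PRR / chi2 from first principles.
# Independent of build_contingency / compute_* internals.
brute_force_stats <- function(events, term_col = "pt") {
  key <- paste(events$primaryid, events[[term_col]], sep = "\r")
  keep <- !duplicated(key) & !is.na(events[[term_col]])
  ev <- events[keep, ]
  terms <- sort(unique(ev[[term_col]]))
  n_total <- as.numeric(nrow(ev))
  target_pairs <- as.numeric(sum(ev$is_target))
  out <- lapply(terms, function(tm) {
    rows <- ev[[term_col]] == tm
    a <- as.numeric(sum(rows & ev$is_target))
    if (a == 0) return(NULL)
    c_ <- as.numeric(sum(rows & !ev$is_target))
    b <- target_pairs - a
    d <- n_total - a - b - c_
    ror <- (a * d) / (b * c_)
    prr <- (a / (a + b)) / (c_ / (c_ + d))
    chi2 <- n_total * (a * d - b * c_)^2 /
      ((a + b) * (c_ + d) * (a + c_) * (b + d))
    data.frame(term = tm, a = a, b = b, c = c_, d = d,
               ror = ror, prr = prr, chi2 = chi2)
  })
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

# Numerical-integration oracle for the empirical-Bayes posterior: works on
# the unnormalised posterior density p(lambda) * Poisson(a | lambda * E),
# never through the conjugate closed form used by compute_ebgm().
ebgm_integration_oracle <- function(a, E, prior) {
  dens <- function(l) {
    (prior$p_mix * stats::dgamma(l, prior$alpha1, rate = prior$beta1) +
       (1 - prior$p_mix) * stats::dgamma(l, prior$alpha2, rate = prior$beta2)) *
      exp(a * log(l * E) - l * E - lgamma(a + 1))
  }
  # bracket the posterior support so the quadrature cannot miss a narrow
  # spike; only the bracket uses conjugate quantiles, the values come from
  # integrating the raw density
  lo <- min(stats::qgamma(1e-12, a + prior$alpha1, rate = E + prior$beta1),
            stats::qgamma(1e-12, a + prior$alpha2, rate = E + prior$beta2))
  hi <- max(stats::qgamma(1 - 1e-12, a + prior$alpha1, rate = E + prior$beta1),
            stats::qgamma(1 - 1e-12, a + prior$alpha2, rate = E + prior$beta2))
  z <- stats::integrate(dens, lo, hi, rel.tol = 1e-12,
                        subdivisions = 2000L)$value
  elog <- stats::integrate(function(l) log(l) * dens(l), lo, hi,
                           rel.tol = 1e-12,
                           subdivisions = 2000L)$value / z
  cdf <- function(x) {
    stats::integrate(dens, lo, x, rel.tol = 1e-12,
                     subdivisions = 2000L)$value / z - 0.05
  }
  q05 <- stats::uniroot(cdf, lower = lo, upper = hi, tol = 1e-12)$root
  list(ebgm = exp(elog), ebgm05 = q05)
}

# random record tables for IO round-trip checks
random_records <- function(kind, n, seed) {
  set.seed(seed)
  pid <- as.character(sample(1e6:2e6, n))
  cid <- as.character(sample(1e5:2e5, n, replace = TRUE))
  rdate <- function(n) {
    format(as.Date("2010-01-01") + sample.int(5000, n, replace = TRUE), "%Y%m%d")
  }
  switch(kind,
    demo = tibble::tibble(
      primaryid = pid, caseid = cid, fda_dt = rdate(n), event_dt = rdate(n),
      sex = sample(c("F", "M", NA), n, replace = TRUE),
      age = sample(c(NA, 1:90), n, replace = TRUE) * 1.0,
      age_cod = sample(c("YR", "MON", NA), n, replace = TRUE),
      reporter_country = sample(c("US", "GB", NA), n, replace = TRUE),
      occp_cod = sample(c("MD", "CN", NA), n, replace = TRUE)
    ),
    drug = tibble::tibble(
      primaryid = pid, caseid = cid,
      drug_seq = sample.int(5, n, replace = TRUE),
      role_cod = sample(c("PS", "SS", "C", "I"), n, replace = TRUE),
      drugname = sample(c("ISOTRETINOIN", "DRUG ALPHA", "ASPIRIN"), n, replace = TRUE),
      prod_ai = sample(c("ISOTRETINOIN", NA), n, replace = TRUE)
    ),
    reac = tibble::tibble(
      primaryid = pid, caseid = cid,
      pt = sample(default_pt_catalog()$pt, n, replace = TRUE)
    ),
    ther = tibble::tibble(
      primaryid = pid, caseid = cid,
      dsg_drug_seq = sample.int(5, n, replace = TRUE),
      start_dt = ifelse(runif(n) < 0.2, NA, rdate(n)),
      end_dt = ifelse(runif(n) < 0.5, NA, rdate(n))
    ),
    outc = tibble::tibble(
      primaryid = pid, caseid = cid,
      outc_cod = sample(c("DE", "LT", "HO", "DS", "CA", "RI", "OT"), n, replace = TRUE)
    ),
    indi = tibble::tibble(
      primaryid = pid, caseid = cid,
      indi_drug_seq = sample.int(5, n, replace = TRUE),
      indi_pt = sample(c("Acne", "Rosacea"), n, replace = TRUE)
    )
  )
}
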