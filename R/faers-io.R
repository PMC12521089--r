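#' @importFrom rlang .data %||%
#' @import dplyr
#' @importFrom tibble tibble as_tibble
NULL

# Modeled schema of the six FAERS quarterly ASCII tables. `required` columns
# must be present in the header; `optional` columns are filled with NA when a
# quarter omits them; unknown extra columns are passed through untouched.
faers_table_schema <- list(
  demo = list(
    required = c("primaryid", "caseid", "fda_dt"),
    optional = c("event_dt", "sex", "age", "age_cod", "reporter_country", "occp_cod"),
    dates = c("fda_dt", "event_dt"),
    numeric = "age",
    coded = list(
      sex = c("F", "M"),
      age_cod = c("DEC", "YR", "MON", "WK", "DY", "HR")
    )
  ),
  drug = list(
    required = c("primaryid", "caseid", "drug_seq", "role_cod", "drugname"),
    optional = "prod_ai",
    integer = "drug_seq",
    coded = list(role_cod = c("PS", "SS", "C", "I"))
  ),
  reac = list(required = c("primaryid", "caseid", "pt")),
  ther = list(
    required = c("primaryid", "caseid", "dsg_drug_seq"),
    optional = c("start_dt", "end_dt"),
    dates = c("start_dt", "end_dt"),
    integer = "dsg_drug_seq"
  ),
  outc = list(
    required = c("primaryid", "caseid", "outc_cod"),
    coded = list(outc_cod = c("DE", "LT", "HO", "DS", "CA", "RI", "OT"))
  ),
  indi = list(
    required = c("primaryid", "caseid", "indi_pt"),
    optional = "indi_drug_seq",
    columns = c("primaryid", "caseid", "indi_drug_seq", "indi_pt"),
    integer = "indi_drug_seq"
  )
)

faers_kinds <- function() names(faers_table_schema)

check_kind <- function(kind) {
  kind <- tolower(kind)
  if (!kind %in% faers_kinds()) {
    stop("unknown FAERS table kind '", kind, "'; expected one of ",
         paste(toupper(faers_kinds()), collapse = ", "), call. = FALSE)
  }
  kind
}

#' Read a FAERS quarterly ASCII table
#'
#' Parses one "$"-delimited FAERS table (DEMO, DRUG, REAC, THER, OUTC or
#' INDI). Column-name matching is case-insensitive; modeled columns are typed
#' and validated, unknown extra columns are preserved as character. Empty
#' fields become `NA` — downstream code never sees empty-string sentinels.
#' Date fields that are not valid FAERS dates (8-digit full dates must be
#' real calendar dates; 6- and 4-digit partial dates are kept) are set to
#' `NA`; the number of such repairs is reported in one warning and stored in
#' the `n_date_warnings` attribute.
#'
#' @param path Path to the table file. The first line must be the
#'   "$"-delimited header.
#' @param kind Table kind, one of `"demo"`, `"drug"`, `"reac"`, `"ther"`,
#'   `"outc"`, `"indi"` (case-insensitive).
#' @return A tibble with the modeled columns for `kind` first (missing
#'   optional columns filled with `NA`), then any passthrough columns.
#' @seealso [write_faers_table()], [read_lookup_tables()]
#' @export
read_faers_table <- function(path, kind) {
  kind <- check_kind(kind)
  schema <- faers_table_schema[[kind]]
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)

  raw <- readr::read_delim(
    path, delim = "$", quote = "", col_types = readr::cols(.default = "c"),
    na = character(), progress = FALSE, show_col_types = FALSE
  )
  names(raw) <- tolower(trimws(names(raw)))

  missing_cols <- setdiff(schema$required, names(raw))
  if (length(missing_cols) > 0) {
    stop("FAERS ", toupper(kind), " table at '", path,
         "' is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }

  modeled <- schema$columns %||% c(schema$required, schema$optional)
  for (col in setdiff(modeled, names(raw))) raw[[col]] <- NA_character_
  out <- raw[c(modeled, setdiff(names(raw), modeled))]

  # blank -> missing marker
  out <- dplyr::mutate(out, dplyr::across(
    dplyr::everything(), ~ dplyr::if_else(trimws(.x) == "", NA_character_, .x)
  ))

  n_bad_dates <- 0L
  for (col in schema$dates) {
    x <- out[[col]]
    bad <- !is.na(x) & !valid_faers_date(x)
    n_bad_dates <- n_bad_dates + sum(bad)
    x[bad] <- NA_character_
    out[[col]] <- x
  }
  if (n_bad_dates > 0) {
    warning(n_bad_dates, " unparseable date value(s) set to missing in ",
            toupper(kind), " table", call. = FALSE)
  }

  for (col in schema$integer) {
    out[[col]] <- suppressWarnings(as.integer(out[[col]]))
  }
  for (col in schema$numeric) {
    out[[col]] <- suppressWarnings(as.numeric(out[[col]]))
  }
  for (col in names(schema$coded)) {
    x <- toupper(trimws(out[[col]]))
    x[!is.na(x) & !x %in% schema$coded[[col]]] <- NA_character_
    out[[col]] <- x
  }

  out <- as_tibble(out)
  attr(out, "n_date_warnings") <- n_bad_dates
  out
}

#' Write a FAERS quarterly ASCII table
#'
#' Emits the "$"-delimited dialect: header first, one row per record, missing
#' values as empty fields, no quoting. Because the dialect has no escape
#' mechanism, any field value containing the "$" delimiter is an error rather
#' than silent corruption.
#'
#' @param records Data frame of records of one kind (e.g. from
#'   [read_faers_table()] or [simulate_faers()]).
#' @param path Output file path.
#' @param kind Table kind; see [read_faers_table()].
#' @return `path`, invisibly.
#' @export
write_faers_table <- function(records, path, kind) {
  kind <- check_kind(kind)
  schema <- faers_table_schema[[kind]]
  records <- as_tibble(records)

  missing_cols <- setdiff(schema$required, names(records))
  if (length(missing_cols) > 0) {
    stop("records lack required ", toupper(kind), " column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  modeled <- schema$columns %||% c(schema$required, schema$optional)
  for (col in setdiff(modeled, names(records))) records[[col]] <- NA_character_
  records <- records[c(modeled, setdiff(names(records), modeled))]

  chr <- dplyr::mutate(records, dplyr::across(dplyr::everything(), ~ {
    x <- as.character(.x)
    dplyr::if_else(is.na(x), "", x)
  }))
  for (col in names(chr)) {
    if (any(grepl("$", chr[[col]], fixed = TRUE))) {
      stop("field '", col, "' contains the '$' delimiter; the FAERS ASCII ",
           "dialect cannot represent it", call. = FALSE)
    }
  }
  lines <- c(
    paste(names(chr), collapse = "$"),
    if (nrow(chr) > 0) do.call(paste, c(unname(as.list(chr)), sep = "$"))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Lookup tables for term standardisation and cohort construction
#'
#' Bundles the four user-supplied lookups the pipeline consumes: the MedDRA
#' Preferred Term to System Organ Class map, the Important Medical Event (IME)
#' term list, the drug-label adverse-event list, and the drug synonym list
#' (trade and generic names). MedDRA and the official IME list are licensed
#' products; they are consumed here as plain CSV exports the user supplies.
#'
#' `read_lookup_tables()` reads them from CSV files with headers `pt,soc`
#' (map), `pt` (IME list), `pt` (label list) and `name` (synonyms);
#' `faers_lookups()` builds the same object from in-memory vectors/frames.
#'
#' @param pt_to_soc Data frame with columns `pt`, `soc`, or path to its CSV.
#' @param ime Character vector of IME Preferred Terms, or path to its CSV.
#' @param label Character vector of on-label Preferred Terms, or path.
#' @param synonyms Character vector of drug names, or path to its CSV.
#' @return An object of class `faers_lookups`: a list with elements
#'   `pt_to_soc` (tibble), `ime`, `label`, `synonyms` (character vectors).
#' @export
faers_lookups <- function(pt_to_soc = NULL, ime = character(),
                          label = character(), synonyms = character()) {
  if (is.null(pt_to_soc)) {
    pt_to_soc <- tibble(pt = character(), soc = character())
  }
  pt_to_soc <- as_tibble(pt_to_soc)
  if (!all(c("pt", "soc") %in% names(pt_to_soc))) {
    stop("pt_to_soc must have columns 'pt' and 'soc'", call. = FALSE)
  }
  structure(
    list(
      pt_to_soc = dplyr::distinct(pt_to_soc[c("pt", "soc")]),
      ime = unique(as.character(ime)),
      label = unique(as.character(label)),
      synonyms = unique(as.character(synonyms))
    ),
    class = "faers_lookups"
  )
}

#' @rdname faers_lookups
#' @export
read_lookup_tables <- function(pt_to_soc = NULL, ime = NULL, label = NULL,
                               synonyms = NULL) {
  read_csv_quiet <- function(p) {
    readr::read_csv(p, col_types = readr::cols(.default = "c"),
                    progress = FALSE, show_col_types = FALSE)
  }
  pull_col <- function(p, col, what) {
    d <- read_csv_quiet(p)
    names(d) <- tolower(names(d))
    if (!col %in% names(d)) {
      stop(what, " CSV at '", p, "' must have a '", col, "' column",
           call. = FALSE)
    }
    d[[col]]
  }
  map <- NULL
  if (!is.null(pt_to_soc)) {
    map <- read_csv_quiet(pt_to_soc)
    names(map) <- tolower(names(map))
  }
  faers_lookups(
    pt_to_soc = map,
    ime = if (is.null(ime)) character() else pull_col(ime, "pt", "IME list"),
    label = if (is.null(label)) character() else pull_col(label, "pt", "label list"),
    synonyms = if (is.null(synonyms)) character() else pull_col(synonyms, "name", "synonym list")
  )
}

#' @export
print.faers_lookups <- function(x, ...) {
  cat("<faers_lookups>\n",
      "  PT->SOC map:  ", nrow(x$pt_to_soc), " terms\n",
      "  IME list:     ", length(x$ime), " terms\n",
      "  label list:   ", length(x$label), " terms\n",
      "  synonyms:     ", length(x$synonyms), " names\n", sep = "")
  invisible(x)
}

#' Read or write a full set of FAERS tables
#'
#' Convenience wrappers over [read_faers_table()] / [write_faers_table()] for
#' a directory holding one file per table kind (`demo.txt`, `drug.txt`, ...).
#'
#' @param dir Directory containing (or to receive) the six table files.
#' @param tables Named list of tibbles (`demo`, `drug`, `reac`, `ther`,
#'   `outc`, `indi`), e.g. the `tables` element of [simulate_faers()].
#' @return `read_faers_tables()` returns a named list of tibbles;
#'   `write_faers_tables()` returns `dir` invisibly.
#' @export
read_faers_tables <- function(dir) {
  out <- lapply(faers_kinds(), function(k) {
    read_faers_table(file.path(dir, paste0(k, ".txt")), k)
  })
  stats::setNames(out, faers_kinds())
}

#' @rdname read_faers_tables
#' @export
write_faers_tables <- function(tables, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (k in faers_kinds()) {
    if (is.null(tables[[k]])) stop("tables is missing component '", k, "'", call. = FALSE)
    write_faers_table(tables[[k]], file.path(dir, paste0(k, ".txt")), k)
  }
  invisible(dir)
}
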