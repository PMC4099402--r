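#' Claims datasets
#'
#' A claims dataset bundles one ambulatory-visit table and one
#' prescription-item table, the two delimited files this package reads and
#' writes, plus the item catalog implied by the item rows.
#'
#' `visits` columns: `visit_id` (unique), `patient_id`, `visit_date` (Date),
#' `dx1`..`dx3` (ICD-9, canonical dotted form; `dx1` required, position 1 is
#' the primary diagnosis), `modality` (semicolon-joined subset of
#' CHM/ACUPUNCTURE/MASSAGE).
#'
#' `items` columns: `visit_id`, `chm_id`, `chm_name`, `chm_type` (HF = herbal
#' formula, SH = single herb), `dose_g_per_day` (>= 0), `duration_days`
#' (integer >= 1), `admin_per_day` (integer >= 1, administrations per day).
#'
#' Invariants enforced on construction: visit ids unique; 1-3 diagnoses per
#' visit; a visit has item rows if and only if CHM is among its modalities;
#' no duplicate `chm_id` within one visit's items; every `chm_id` maps to a
#' single (name, type) pair in the catalog.
#'
#' @param visits Tibble of visits (schema above).
#' @param items Tibble of prescription items (schema above).
#' @return An object of class `claims_dataset`: a list with elements
#'   `visits`, `items`, and `catalog` (tibble `chm_id`, `chm_name`,
#'   `chm_type`).
#' @seealso [read_claims()], [write_claims()]
#' @export
claims_dataset <- function(visits, items) {
  visits <- tibble::as_tibble(visits)
  items <- tibble::as_tibble(items)
  validate_visits(visits)
  validate_items(items, visits)
  structure(
    list(visits = visits, items = items, catalog = build_catalog(items)),
    class = "claims_dataset"
  )
}

#' @export
print.claims_dataset <- function(x, ...) {
  cat(sprintf(
    "<claims_dataset> %d visits, %d patients, %d item rows, %d distinct CHM\n",
    nrow(x$visits), dplyr::n_distinct(x$visits$patient_id),
    nrow(x$items), nrow(x$catalog)
  ))
  invisible(x)
}

VISITS_SCHEMA <- c("visit_id", "patient_id", "visit_date",
                   "dx1", "dx2", "dx3", "modality")
ITEMS_SCHEMA <- c("visit_id", "chm_id", "chm_name", "chm_type",
                  "dose_g_per_day", "duration_days", "admin_per_day")

check_schema <- function(found, expected, what) {
  missing <- setdiff(expected, found)
  extra <- setdiff(found, expected)
  if (length(missing) || length(extra)) {
    stop(sprintf(
      "schema error in %s table: %s%s", what,
      if (length(missing)) paste0("missing column(s) ",
                                  paste(missing, collapse = ", ")) else "",
      if (length(extra)) paste0(if (length(missing)) "; " else "",
                                "unexpected column(s) ",
                                paste(extra, collapse = ", ")) else ""
    ), call. = FALSE)
  }
  invisible(TRUE)
}

parse_error <- function(what, column, lines) {
  stop(sprintf("parse error in %s table, column %s, line(s) %s",
               what, column, paste(lines + 1L, collapse = ", ")),
       call. = FALSE) # +1: header line, so reported numbers match the file
}

# coerce a character column to numeric, reporting 1-based data-row indices
# of values that fail to parse
numeric_column <- function(x, what, column) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad)) parse_error(what, column, bad)
  out
}

validate_visits <- function(visits) {
  check_schema(names(visits), VISITS_SCHEMA, "visits")
  if (anyDuplicated(visits$visit_id)) {
    stop("visits table: duplicate visit_id values", call. = FALSE)
  }
  if (any(is.na(visits$dx1))) {
    stop("visits table: dx1 (primary diagnosis) is required on every row",
         call. = FALSE)
  }
  # dx positions must be left-filled: no dx3 without dx2
  if (any(is.na(visits$dx2) & !is.na(visits$dx3))) {
    stop("visits table: dx3 present without dx2", call. = FALSE)
  }
  mods <- modality_list(visits$modality)
  bad <- which(vapply(mods, function(m) any(!m %in% MODALITIES), logical(1)))
  if (length(bad)) {
    stop(sprintf("visits table: unknown modality value on row(s) %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

validate_items <- function(items, visits) {
  check_schema(names(items), ITEMS_SCHEMA, "items")
  unknown <- setdiff(items$visit_id, visits$visit_id)
  if (length(unknown)) {
    stop(sprintf("referential error: item rows reference unknown visit_id %s",
                 paste(utils::head(unknown, 5), collapse = ", ")),
         call. = FALSE)
  }
  if (anyDuplicated(items[c("visit_id", "chm_id")])) {
    dup <- items[duplicated(items[c("visit_id", "chm_id")]), ]
    stop(sprintf(
      "duplicate chm_id within one visit's items (e.g. visit %s, chm %s)",
      dup$visit_id[1], dup$chm_id[1]), call. = FALSE)
  }
  if (any(!items$chm_type %in% c("HF", "SH"))) {
    stop("items table: chm_type must be HF or SH", call. = FALSE)
  }
  if (any(items$dose_g_per_day < 0)) {
    stop("items table: dose_g_per_day must be non-negative", call. = FALSE)
  }
  if (any(items$duration_days < 1 | items$duration_days %% 1 != 0)) {
    stop("items table: duration_days must be a positive integer",
         call. = FALSE)
  }
  if (any(items$admin_per_day < 1 | items$admin_per_day %% 1 != 0)) {
    stop("items table: admin_per_day must be a positive integer",
         call. = FALSE)
  }
  # items nonempty iff CHM modality
  chm_visits <- visits$visit_id[has_modality(visits$modality, "CHM")]
  with_items <- unique(items$visit_id)
  missing_items <- setdiff(chm_visits, with_items)
  if (length(missing_items)) {
    stop(sprintf("visit(s) with CHM modality but no items: %s",
                 paste(utils::head(missing_items, 5), collapse = ", ")),
         call. = FALSE)
  }
  stray <- setdiff(with_items, chm_visits)
  if (length(stray)) {
    stop(sprintf("visit(s) with items but no CHM modality: %s",
                 paste(utils::head(stray, 5), collapse = ", ")),
         call. = FALSE)
  }
  invisible(TRUE)
}

build_catalog <- function(items) {
  catalog <- dplyr::distinct(items, .data$chm_id, .data$chm_name,
                             .data$chm_type)
  clash <- catalog$chm_id[duplicated(catalog$chm_id)]
  if (length(clash)) {
    stop(sprintf("catalog conflict: chm_id %s mapped to multiple (name, type)",
                 paste(unique(clash), collapse = ", ")), call. = FALSE)
  }
  dplyr::arrange(catalog, .data$chm_id)
}

#' Read a claims dataset from delimited files
#'
#' Reads the two-file claims format (comma-separated UTF-8 with a header
#' row, ISO-8601 dates) into a validated [claims_dataset()]. Diagnosis codes
#' are normalized to the dotted canonical form on read, so "6254" and
#' "625.4" load identically. Row order is preserved.
#'
#' @param visits_path Path to the visits CSV.
#' @param items_path Path to the prescription-items CSV.
#' @return A `claims_dataset`.
#' @examples
#' paths <- example_claims_paths()
#' read_claims(paths$visits, paths$items)
#' @export
read_claims <- function(visits_path, items_path) {
  for (p in c(visits_path, items_path)) {
    if (!file.exists(p)) stop(sprintf("file not found: %s", p), call. = FALSE)
  }
  visits_raw <- readr::read_csv(visits_path, col_types = readr::cols(
    .default = readr::col_character()))
  items_raw <- readr::read_csv(items_path, col_types = readr::cols(
    .default = readr::col_character()))
  check_schema(names(visits_raw), VISITS_SCHEMA, "visits")
  check_schema(names(items_raw), ITEMS_SCHEMA, "items")

  dates <- as.Date(visits_raw$visit_date, format = "%Y-%m-%d")
  bad <- which(is.na(dates))
  if (length(bad)) parse_error("visits", "visit_date", bad)

  visits <- tibble::tibble(
    visit_id = visits_raw$visit_id,
    patient_id = visits_raw$patient_id,
    visit_date = dates,
    dx1 = normalize_icd9(visits_raw$dx1),
    dx2 = normalize_icd9(visits_raw$dx2),
    dx3 = normalize_icd9(visits_raw$dx3),
    modality = visits_raw$modality
  )
  items <- tibble::tibble(
    visit_id = items_raw$visit_id,
    chm_id = items_raw$chm_id,
    chm_name = items_raw$chm_name,
    chm_type = items_raw$chm_type,
    dose_g_per_day = numeric_column(items_raw$dose_g_per_day,
                                    "items", "dose_g_per_day"),
    duration_days = numeric_column(items_raw$duration_days,
                                   "items", "duration_days"),
    admin_per_day = numeric_column(items_raw$admin_per_day,
                                   "items", "admin_per_day")
  )
  claims_dataset(visits, items)
}

#' Write a claims dataset to delimited files
#'
#' Inverse of [read_claims()]: emits the visits and items tables as
#' comma-separated UTF-8 with header rows and ISO-8601 dates, such that
#' reading the files back reproduces the dataset field for field.
#'
#' @param data A `claims_dataset`.
#' @param visits_path,items_path Output paths.
#' @return Invisibly, a character vector of the two paths written.
#' @export
write_claims <- function(data, visits_path, items_path) {
  stopifnot(inherits(data, "claims_dataset"))
  visits <- dplyr::mutate(data$visits,
                          visit_date = format(.data$visit_date, "%Y-%m-%d"))
  readr::write_csv(visits, visits_path, na = "")
  readr::write_csv(data$items, items_path, na = "")
  invisible(c(visits_path, items_path))
}

#' Write a uniform table of records as delimited text
#'
#' General writer for the package's result tables: a header row, fixed
#' column order, and percentage columns (names ending in `_pct`) rendered to
#' one decimal place (half-up). Input may be a data frame or a list of
#' identically named records (each coerced to one row).
#'
#' @param rows Data frame, or list of named lists sharing one schema.
#' @param path Output path.
#' @return Invisibly, the tibble that was written.
#' @export
write_table <- function(rows, path) {
  if (is.data.frame(rows)) {
    tab <- tibble::as_tibble(rows)
  } else if (is.list(rows)) {
    if (length(rows) == 0) {
      stop("schema error: empty record list has no schema; ",
           "pass a zero-row data frame to write a header-only file",
           call. = FALSE)
    }
    schemas <- lapply(rows, names)
    if (!all(vapply(schemas, identical, logical(1), y = schemas[[1]]))) {
      stop("schema error: records do not share one set of column names",
           call. = FALSE)
    }
    tab <- dplyr::bind_rows(lapply(rows, tibble::as_tibble))
  } else {
    stop("rows must be a data frame or a list of records", call. = FALSE)
  }
  pct_cols <- grep("_pct$", names(tab), value = TRUE)
  for (col in pct_cols) {
    if (is.numeric(tab[[col]])) {
      tab[[col]] <- ifelse(is.na(tab[[col]]), NA_character_,
                           sprintf("%.1f", round_half_up(tab[[col]], 1)))
    }
  }
  readr::write_csv(tab, path, na = "")
  invisible(tab)
}

#' Read back a table written by [write_table()]
#'
#' @param path Path to a CSV produced by [write_table()].
#' @return A tibble with column types guessed by readr (percent columns come
#'   back numeric at one decimal).
#' @export
read_table <- function(path) {
  readr::read_csv(path, col_types = readr::cols(), show_col_types = FALSE)
}

#' Paths to the bundled two-visit example claims files
#'
#' A miniature hand-written pair of claims files used in documentation
#' examples and round-trip tests.
#'
#' @return List with elements `visits` and `items`.
#' @export
example_claims_paths <- function() {
  list(
    visits = system.file("extdata", "example_visits.csv",
                         package = "herbmine", mustWork = TRUE),
    items = system.file("extdata", "example_items.csv",
                        package = "herbmine", mustWork = TRUE)
  )
}
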