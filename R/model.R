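# Data model and delimited-text IO.
#
# A response table holds one row per screener or survey submission. Raw
# columns are kept verbatim (timestamps as strings, zip as a string so leading
# zeros survive); derived columns (`client_ts`, `server_ts`, `submit_ts`,
# `has_timestamp_info`, `disparity_min`, `zip_malformed`) are recomputed on
# load and stripped again on write, so a write/load cycle is lossless.

response_base_columns <- c(
  "record_id", "form", "linked_screener_id",
  "client_timestamp", "server_timestamp", "submit_instant",
  "completion_minutes", "counties_marked", "zip", "heard_source",
  "captcha_passed", "honeypot_value",
  "email", "phone", "postal_address", "ip_hash",
  "child_age_years", "child_grade", "open_text")

derived_columns <- c("client_ts", "server_ts", "submit_ts",
                     "has_timestamp_info", "disparity_min", "zip_malformed")

#' Attach derived columns to a raw response table
#'
#' Parses timestamps, flags rows without usable time-zone information, computes
#' the client/server disparity in minutes, and flags malformed zip codes
#' (anything not matching `^\\d{5}$`). Malformed values are retained, never
#' dropped: they are evidence for the detectors.
#'
#' @param tbl A tibble with (at least) `record_id` and `form` columns.
#' @return The same tibble with derived columns, classed `response_tbl`.
#' @export
as_response_tbl <- function(tbl) {
  tbl <- tibble::as_tibble(tbl)
  for (col in setdiff(response_base_columns, names(tbl))) {
    tbl[[col]] <- if (col == "completion_minutes") NA_real_
      else if (col == "captcha_passed") NA
      else if (col %in% c("child_age_years", "child_grade")) NA_integer_
      else NA_character_
  }
  tbl$completion_minutes <- suppressWarnings(as.numeric(tbl$completion_minutes))
  tbl$captcha_passed <- parse_logical(tbl$captcha_passed)
  tbl$child_age_years <- suppressWarnings(as.integer(tbl$child_age_years))
  tbl$child_grade <- suppressWarnings(as.integer(tbl$child_grade))
  tbl$client_ts <- parse_ts(tbl$client_timestamp)
  tbl$server_ts <- parse_ts(tbl$server_timestamp)
  tbl$submit_ts <- parse_ts(tbl$submit_instant)
  tbl$has_timestamp_info <- !is.na(tbl$client_ts) & !is.na(tbl$server_ts)
  tbl$disparity_min <- disparity_minutes(tbl$client_ts, tbl$server_ts)
  tbl$zip_malformed <- !is.na(tbl$zip) & !grepl("^[0-9]{5}$", tbl$zip)
  class(tbl) <- unique(c("response_tbl", class(tbl)))
  tbl
}

parse_logical <- function(x) {
  if (is.logical(x)) return(x)
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[x %in% c("true", "t", "1", "yes")] <- TRUE
  out[x %in% c("false", "f", "0", "no")] <- FALSE
  out
}

#' Construct a single response record
#'
#' Convenience constructor for tests and worked examples: returns a one-row
#' [as_response_tbl()] table with internally consistent defaults (a clean
#' survey record), overridable field by field. Speed-bump answers are columns
#' named `sb_<id>`, survey items are columns named `item_<id>`.
#'
#' @param ... Named fields overriding the defaults.
#' @return A one-row `response_tbl`.
#' @export
#' @examples
#' response_record(completion_minutes = 5)
response_record <- function(...) {
  defaults <- list(
    record_id = "R00001", form = "survey", linked_screener_id = NA_character_,
    client_timestamp = "2022-02-01T12:00:00+0000",
    server_timestamp = "2022-02-01T12:00:00+0000",
    submit_instant = "2022-02-01T12:00:00+0000",
    completion_minutes = 17, counties_marked = "County01", zip = "20601",
    heard_source = "community_flyer", captcha_passed = TRUE,
    honeypot_value = "", email = "jane.doe11@example.org",
    phone = "410-555-0001", postal_address = "101 Main St",
    ip_hash = "", child_age_years = 10L, child_grade = 5L,
    open_text = "")
  over <- list(...)
  bad <- names(over)[!nzchar(names(over) %||% "")]
  if (length(over) && (is.null(names(over)) || any(!nzchar(names(over)))))
    stop("all fields passed to response_record() must be named")
  defaults[names(over)] <- over
  as_response_tbl(tibble::as_tibble(defaults))
}

#' Load a response export
#'
#' Reads a delimited-text export (RFC-4180-style CSV by default, header row
#' required), applies an optional column mapping, and validates the schema.
#' Malformed timestamps and zips are retained and flagged, not rejected.
#'
#' @param path Path to the delimited file.
#' @param schema Optional named character vector mapping canonical field names
#'   to the file's column names, e.g. `c(record_id = "ResponseId")`.
#' @param delim Field delimiter, default `","`.
#' @return A `response_tbl` tibble, one row per record.
#' @export
load_responses <- function(path, schema = NULL, delim = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readr::read_delim(path, delim = delim,
                           col_types = readr::cols(.default = readr::col_character()),
                           show_col_types = FALSE, progress = FALSE)
  if (!is.null(schema)) {
    schema <- schema[!is.na(schema) & nzchar(schema)]
    missing_src <- schema[!schema %in% names(raw)]
    if (length(missing_src))
      stop("schema maps to absent column(s): ", paste(missing_src, collapse = ", "))
    names(raw)[match(schema, names(raw))] <- names(schema)
  }
  required <- c("record_id", "form")
  absent <- setdiff(required, names(raw))
  if (length(absent))
    stop("missing required column(s): ", paste(absent, collapse = ", "))
  dup <- unique(raw$record_id[duplicated(raw$record_id)])
  if (length(dup))
    stop("duplicate record_id(s): ", paste(dup, collapse = ", "))
  bad_form <- setdiff(unique(raw$form), c("screener", "survey"))
  if (length(bad_form))
    stop("form must be 'screener' or 'survey'; saw: ",
         paste(bad_form, collapse = ", "))
  as_response_tbl(raw)
}

#' Write a response table back to delimited text
#'
#' Drops the derived columns and writes the raw fields, so that
#' `load_responses()` of the result reproduces the table exactly.
#'
#' @param records A `response_tbl`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_responses <- function(records, path) {
  out <- records[setdiff(names(records), derived_columns)]
  readr::write_csv(out, path, na = "")
  invisible(path)
}

# ---- reference tables -------------------------------------------------------

#' Zip-to-county lookup
#'
#' @param entries Named character vector: names are 5-digit zip strings, values
#'   county names. Each zip maps to exactly one county.
#' @param eligible_counties Character vector of study-eligible county names.
#' @return An object of class `zip_county_map`.
#' @export
zip_county_map <- function(entries, eligible_counties) {
  stopifnot(is.character(entries), !is.null(names(entries)))
  if (anyDuplicated(names(entries)))
    stop("duplicate zip(s) in map: ",
         paste(unique(names(entries)[duplicated(names(entries))]), collapse = ", "))
  eligible_counties <- unique(as.character(eligible_counties))
  orphan <- setdiff(eligible_counties, unname(entries))
  if (length(orphan))
    sg_log(paste0("eligible county without any zip in map: ",
                  paste(orphan, collapse = ", ")), "warn")
  structure(list(entries = entries, eligible_counties = eligible_counties),
            class = "zip_county_map")
}

#' @export
print.zip_county_map <- function(x, ...) {
  cat(sprintf("<zip_county_map> %d zips, %d counties (%d eligible)\n",
              length(x$entries), length(unique(x$entries)),
              length(x$eligible_counties)))
  invisible(x)
}

#' Load a zip-to-county map from a two-column file
#'
#' @param path Delimited file with columns `zip` and `county`.
#' @param eligible_counties Character vector of eligible county names.
#' @param delim Field delimiter.
#' @return A [zip_county_map()]. Duplicate zip rows mapping one zip to two
#'   different counties are a load error; identical duplicates are collapsed.
#' @export
load_zip_county_map <- function(path, eligible_counties, delim = ",") {
  tbl <- readr::read_delim(path, delim = delim,
                           col_types = readr::cols(.default = readr::col_character()),
                           show_col_types = FALSE, progress = FALSE)
  absent <- setdiff(c("zip", "county"), names(tbl))
  if (length(absent))
    stop("zip map missing column(s): ", paste(absent, collapse = ", "))
  tbl <- unique(tbl[c("zip", "county")])
  conf <- unique(tbl$zip[duplicated(tbl$zip)])
  if (length(conf))
    stop("zip(s) mapped to more than one county: ", paste(conf, collapse = ", "))
  zip_county_map(setNames(tbl$county, tbl$zip), eligible_counties)
}

#' Recruitment-channel activity calendar
#'
#' @param channels Data frame with columns `channel`, `start`, `end` (Dates);
#'   one row per active interval.
#' @param never_used Character vector of channel names that were never used
#'   (false/impossible answer options on the screener).
#' @return An object of class `channel_calendar`.
#' @export
channel_calendar <- function(channels, never_used = character()) {
  channels <- tibble::as_tibble(channels)
  stopifnot(all(c("channel", "start", "end") %in% names(channels)))
  channels$start <- as.Date(channels$start)
  channels$end <- as.Date(channels$end)
  if (any(channels$start > channels$end, na.rm = TRUE))
    stop("calendar interval with start > end")
  never_used <- unique(as.character(never_used))
  clash <- intersect(never_used, channels$channel)
  if (length(clash))
    stop("never-used channel(s) also have active intervals: ",
         paste(clash, collapse = ", "))
  structure(list(channels = channels, never_used = never_used),
            class = "channel_calendar")
}

#' @export
print.channel_calendar <- function(x, ...) {
  cat(sprintf("<channel_calendar> %d channel(s) with intervals, %d never used\n",
              length(unique(x$channels$channel)), length(x$never_used)))
  invisible(x)
}

#' Load a channel calendar
#'
#' File columns: `channel,start,end`. Rows with empty `start` and `end` mark a
#' channel as never used.
#'
#' @param path Delimited file path.
#' @param delim Field delimiter.
#' @return A [channel_calendar()].
#' @export
load_channel_calendar <- function(path, delim = ",") {
  tbl <- readr::read_delim(path, delim = delim,
                           col_types = readr::cols(.default = readr::col_character()),
                           show_col_types = FALSE, progress = FALSE)
  absent <- setdiff(c("channel", "start", "end"), names(tbl))
  if (length(absent))
    stop("calendar missing column(s): ", paste(absent, collapse = ", "))
  never <- is_blank(tbl$start) & is_blank(tbl$end)
  channel_calendar(tbl[!never, , drop = FALSE], never_used = tbl$channel[never])
}

#' Speed-bump answer key
#'
#' @param key Named list: names are speed-bump question ids (matching the
#'   `sb_<id>` response columns), values character vectors of accepted answers.
#'   Matching is case-folded and whitespace-trimmed.
#' @return An object of class `speedbump_key`.
#' @export
speedbump_key <- function(key) {
  stopifnot(is.list(key), !is.null(names(key)))
  key <- lapply(key, function(a) {
    a <- tolower(trimws(as.character(a)))
    a <- a[nzchar(a)]
    if (!length(a)) stop("speed-bump key entry with no accepted answers")
    a
  })
  structure(key, class = "speedbump_key")
}

#' @export
print.speedbump_key <- function(x, ...) {
  cat(sprintf("<speedbump_key> %d question(s): %s\n", length(x),
              paste(names(x), collapse = ", ")))
  invisible(x)
}

#' Load a speed-bump answer key
#'
#' File columns: `question_id,accepted` with accepted answers joined by `;`.
#'
#' @param path Delimited file path.
#' @param delim Field delimiter.
#' @return A [speedbump_key()].
#' @export
load_speedbump_key <- function(path, delim = ",") {
  tbl <- readr::read_delim(path, delim = delim,
                           col_types = readr::cols(.default = readr::col_character()),
                           show_col_types = FALSE, progress = FALSE)
  absent <- setdiff(c("question_id", "accepted"), names(tbl))
  if (length(absent))
    stop("speed-bump key missing column(s): ", paste(absent, collapse = ", "))
  speedbump_key(setNames(strsplit(tbl$accepted, ";", fixed = TRUE),
                         tbl$question_id))
}

#' Write a fraud report table
#'
#' One row per record: `record_id`, `total_points`, `label`, and the fired rule
#' ids joined by `;` in lexicographic order. Rows are ordered by `record_id`
#' so output is bit-stable.
#'
#' @param reports A fraud-report tibble from [run_pipeline()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_report <- function(reports, path) {
  if (is.null(reports) || nrow(reports) == 0)
    stop("cannot write an empty report table")
  stopifnot(all(c("record_id", "total_points", "label", "fired_rules") %in%
                  names(reports)))
  out <- reports[order(reports$record_id),
                 c("record_id", "total_points", "label", "fired_rules")]
  readr::write_csv(out, path, na = "")
  invisible(path)
}
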