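# Points-based scoring and the two-stage eligibility screen.

#' Scoring policy
#'
#' Maps each rule id to its point value and sets the classification cutoff:
#' a record is labelled fraudulent when its total reaches `fraud_threshold`
#' points (default 2), so a single 2-point indicator or any two 1-point
#' indicators suffice.
#'
#' @param points_by_rule Named integer vector of point values per rule id.
#' @param fraud_threshold Integer classification cutoff, default 2.
#' @return An object of class `scoring_policy`.
#' @export
scoring_policy <- function(points_by_rule = default_points(),
                           fraud_threshold = 2L) {
  points_by_rule <- vapply(points_by_rule, as.integer, integer(1))
  if (any(points_by_rule < 0)) stop("point values must be >= 0")
  fraud_threshold <- as.integer(fraud_threshold)
  if (fraud_threshold < 1) stop("fraud_threshold must be >= 1")
  structure(list(points_by_rule = points_by_rule,
                 fraud_threshold = fraud_threshold),
            class = "scoring_policy")
}

#' Default point values per rule
#'
#' @return Named integer vector: 1 point for short_completion,
#'   geo_simultaneous, cluster, odd_email, speedbump, inactive_source, dup_ip
#'   and wave; 2 points for cross_form, dup_text, tz_disparity and
#'   dup_contact; 0 for the honeypot (a screener gate, not a scored
#'   indicator).
#' @export
default_points <- function() {
  c(short_completion = 1L, geo_simultaneous = 1L, cluster = 1L,
    odd_email = 1L, speedbump = 1L, inactive_source = 1L, dup_ip = 1L,
    wave = 1L, cross_form = 2L, dup_text = 2L, tz_disparity = 2L,
    dup_contact = 2L, honeypot = 0L)
}

#' @export
print.scoring_policy <- function(x, ...) {
  cat(sprintf("<scoring_policy> fraudulent at >= %d point(s)\n",
              x$fraud_threshold))
  pts <- x$points_by_rule
  cat(sprintf("  %s\n", paste(sprintf("%s=%d", names(pts), pts),
                              collapse = " ")))
  invisible(x)
}

#' Score one record's rule results
#'
#' Sums the point values of fired rules (taking point values from the policy
#' where the rule id is known to it, otherwise from the result itself) and
#' labels the record fraudulent when the total reaches the policy threshold.
#' At most one result per rule id is allowed — a duplicate indicates an
#' upstream invariant breach and is an error.
#'
#' @param results A rule-result tibble (columns `rule_id`, `fired`, `points`)
#'   for a single record.
#' @param policy A [scoring_policy()].
#' @param record_id Optional record id carried into the report.
#' @return A one-row tibble: `record_id`, `total_points`, `label`,
#'   `fired_rules` (fired rule ids, `;`-joined in lexicographic order).
#' @export
score_response <- function(results, policy = scoring_policy(),
                           record_id = NA_character_) {
  dup <- unique(results$rule_id[duplicated(results$rule_id)])
  if (length(dup))
    stop("duplicate rule result(s) for: ", paste(dup, collapse = ", "))
  pts <- ifelse(results$rule_id %in% names(policy$points_by_rule),
                policy$points_by_rule[results$rule_id], results$points)
  total <- as.integer(sum(pts[results$fired]))
  fired <- sort(results$rule_id[results$fired & pts > 0])
  tibble::tibble(
    record_id = record_id,
    total_points = total,
    label = if (total >= policy$fraud_threshold) "fraudulent" else "legitimate",
    fired_rules = paste(fired, collapse = ";"))
}

#' Screen a single eligibility record
#'
#' First-stage validation of a public screener submission. A record is
#' `ineligible` when its marked county is not eligible, more than one county
#' is marked, the zip is unknown or maps to a different county, the CAPTCHA
#' was not passed, or a speed bump was answered incorrectly. It is `barred` —
#' automated rejection, no survey link issued — when the client/server
#' disparity exceeds the time-zone threshold or the honeypot was answered;
#' barring takes precedence over ineligibility. Otherwise it is `eligible`.
#'
#' @param s A one-row response table with `form == "screener"`.
#' @param zm A [zip_county_map()].
#' @param params [detector_params()].
#' @param key Optional [speedbump_key()]; when `NULL` the speed-bump gate is
#'   skipped.
#' @return A list with `decision` ("eligible", "ineligible" or "barred") and
#'   `reasons` (character vector naming every failed gate).
#' @export
screen_eligibility <- function(s, zm, params = detector_params(), key = NULL) {
  r <- first_row(s)
  if (!identical(r$form, "screener"))
    stop("screen_eligibility() expects a screener record")
  inelig <- character(); barred <- character()
  counties <- trimws(strsplit(r$counties_marked %||% "", ";", fixed = TRUE)[[1]])
  counties <- counties[nzchar(counties)]
  if (length(counties) == 0) {
    inelig <- c(inelig, "no county marked")
  } else if (length(counties) > 1) {
    inelig <- c(inelig, "multiple counties marked")
  } else {
    county <- counties
    if (!(county %in% zm$eligible_counties))
      inelig <- c(inelig, "county not eligible")
    zip <- trimws(r$zip %||% "")
    if (!nzchar(zip) || !(zip %in% names(zm$entries))) {
      inelig <- c(inelig, "unknown zip")
    } else if (zm$entries[[zip]] != county) {
      inelig <- c(inelig, "zip does not match marked county")
    }
  }
  if (!isTRUE(r$captcha_passed)) inelig <- c(inelig, "captcha failed")
  if (!is.null(key) && detect_speedbump_failure(s, key)$fired)
    inelig <- c(inelig, "speed bump failed")
  if (detect_timezone_disparity(s, params)$fired)
    barred <- c(barred,
                sprintf("client-server disparity > %g min",
                        params$tz_disparity_minutes))
  if (detect_honeypot(s)$fired) barred <- c(barred, "honeypot answered")
  decision <- if (length(barred)) "barred"
    else if (length(inelig)) "ineligible" else "eligible"
  list(decision = decision, reasons = c(barred, inelig))
}

#' Run every detector and score every survey record
#'
#' Orchestrates the full points-based review: per-record detectors
#' (completion time, time-zone disparity, email format, recruitment source,
#' speed bumps, honeypot), the cross-form consistency check against each
#' survey's linked screener, and the population detectors (duplicate IP,
#' duplicate contact, duplicate/near-duplicate open text, simultaneous
#' county+zip matches, response clusters, wave timing) over the survey table.
#' Screener records are never scored — barred respondents have no survey
#' record at all.
#'
#' @param screeners,surveys `response_tbl` tables; every
#'   `surveys$linked_screener_id` must exist in `screeners$record_id`.
#' @param refs List of reference tables: `zip_map` (required), `calendar`
#'   and `speedbump_key` (optional; the corresponding rules are skipped when
#'   absent).
#' @param policy A [scoring_policy()].
#' @param params [detector_params()].
#' @return A fraud-report tibble sorted by `record_id` (`record_id`,
#'   `total_points`, `label`, `fired_rules`), with the full per-rule result
#'   table attached as attribute `"details"` (see [report_details()]).
#' @export
run_pipeline <- function(screeners, surveys, refs, policy = scoring_policy(),
                         params = detector_params()) {
  stopifnot(is.list(refs), !is.null(refs$zip_map))
  empty <- tibble::tibble(record_id = character(), total_points = integer(),
                          label = character(), fired_rules = character())
  if (is.null(surveys) || nrow(surveys) == 0) {
    attr(empty, "details") <- tibble::tibble(
      record_id = character(), rule_id = character(), fired = logical(),
      points = integer(), evidence = character())
    return(empty)
  }
  idx <- match(surveys$linked_screener_id, screeners$record_id)
  if (anyNA(idx)) {
    dangling <- surveys$record_id[is.na(idx)]
    stop("survey record(s) reference unknown screener id(s): ",
         paste(dangling, collapse = ", "))
  }
  pop <- dplyr::bind_rows(
    detect_duplicate_ip(surveys),
    detect_duplicate_contact(surveys),
    detect_duplicate_open_text(surveys, params),
    detect_simultaneous_geo_match(surveys, params),
    detect_response_cluster(surveys, params),
    detect_wave_submission(surveys, params))
  sur_rows <- apply(surveys, 1, as.list)
  scr_rows <- apply(screeners, 1, as.list)
  typed <- c("completion_minutes", "child_age_years", "child_grade",
             "captcha_passed", "client_ts", "server_ts", "submit_ts")
  retype <- function(row, tbl, i) {
    for (f in typed) row[[f]] <- tbl[[f]][i]
    row
  }
  per <- lapply(seq_len(nrow(surveys)), function(i) {
    row <- retype(sur_rows[[i]], surveys, i)
    res <- dplyr::bind_rows(
      detect_short_completion(row, params),
      detect_timezone_disparity(row, params),
      detect_unusual_email(row, params),
      if (!is.null(refs$calendar)) detect_inactive_source(row, refs$calendar),
      if (!is.null(refs$speedbump_key))
        detect_speedbump_failure(row, refs$speedbump_key),
      detect_cross_form_inconsistency(row,
                                      retype(scr_rows[[idx[i]]], screeners,
                                             idx[i]),
                                      refs$zip_map),
      detect_honeypot(row))
    res$record_id <- surveys$record_id[i]
    res
  })
  details <- dplyr::bind_rows(
    dplyr::bind_rows(per)[c("record_id", "rule_id", "fired", "points", "evidence")],
    pop)
  if (anyDuplicated(details[c("record_id", "rule_id")]))
    stop("duplicate rule result within a record")
  pts <- ifelse(details$rule_id %in% names(policy$points_by_rule),
                policy$points_by_rule[details$rule_id], details$points)
  ids <- sort(unique(details$record_id))
  totals <- tapply(as.integer(pts) * details$fired, details$record_id, sum)
  fired_join <- vapply(split(details$rule_id[details$fired & pts > 0],
                             factor(details$record_id[details$fired & pts > 0],
                                    levels = ids)),
                       function(r) paste(sort(r), collapse = ";"),
                       character(1))
  reports <- tibble::tibble(
    record_id = ids,
    total_points = as.integer(totals[ids]),
    label = as.vector(ifelse(totals[ids] >= policy$fraud_threshold,
                             "fraudulent", "legitimate")),
    fired_rules = unname(fired_join[ids]))
  attr(reports, "details") <- details[order(details$record_id, details$rule_id), ]
  class(reports) <- unique(c("fraud_report_tbl", class(reports)))
  reports
}

#' Per-rule details behind a fraud report
#'
#' @param reports A report table from [run_pipeline()].
#' @return The long rule-result tibble (`record_id`, `rule_id`, `fired`,
#'   `points`, `evidence`).
#' @export
report_details <- function(reports) {
  d <- attr(reports, "details")
  if (is.null(d)) stop("no details attached to this report table")
  d
}

#' Cohort-level summary counts
#'
#' Mirrors the style of the study's timestamp-disparity table: counts of
#' records with timestamp information, with any client/server disparity, and
#' with disparities over the time-zone threshold, computed over screeners and
#' surveys together, plus per-rule flag counts and the fraudulent total from
#' the report.
#'
#' @param screeners,surveys `response_tbl` tables (either may be empty).
#' @param reports Report table from [run_pipeline()] (may be empty).
#' @param params [detector_params()].
#' @return A tibble with columns `metric` and `count`.
#' @export
summarize_cohort <- function(screeners, surveys, reports,
                             params = detector_params()) {
  all_rec <- dplyr::bind_rows(
    if (!is.null(screeners) && nrow(screeners))
      screeners[c("record_id", "has_timestamp_info", "disparity_min")],
    if (!is.null(surveys) && nrow(surveys))
      surveys[c("record_id", "has_timestamp_info", "disparity_min")])
  n_all <- if (is.null(all_rec)) 0L else nrow(all_rec)
  info <- disp <- over <- 0L
  if (n_all) {
    info <- sum(all_rec$has_timestamp_info, na.rm = TRUE)
    disp <- sum(all_rec$has_timestamp_info & all_rec$disparity_min > 0,
                na.rm = TRUE)
    over <- sum(all_rec$has_timestamp_info &
                  all_rec$disparity_min > params$tz_disparity_minutes,
                na.rm = TRUE)
  }
  rows <- tibble::tibble(
    metric = c("total_records", "with_timestamp_info", "any_disparity",
               paste0("disparity_over_", params$tz_disparity_minutes, "min")),
    count = as.integer(c(n_all, info, disp, over)))
  det <- attr(reports, "details")
  if (!is.null(det) && nrow(det)) {
    per_rule <- tapply(det$fired, det$rule_id, sum)
    rows <- dplyr::bind_rows(rows, tibble::tibble(
      metric = paste0("flagged_", names(per_rule)),
      count = as.integer(per_rule)))
  }
  n_fraud <- if (!is.null(reports) && nrow(reports))
    sum(reports$label == "fraudulent") else 0L
  dplyr::bind_rows(rows, tibble::tibble(metric = "fraudulent",
                                        count = as.integer(n_fraud)))
}

#' Render a summary as an aligned text table
#'
#' @param summary Tibble from [summarize_cohort()].
#' @return Character vector of lines, invisibly printed with `cat()` when
#'   called interactively.
#' @export
format_summary <- function(summary) {
  w <- max(nchar(summary$metric))
  sprintf(paste0("%-", w, "s  %6d"), summary$metric, summary$count)
}
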