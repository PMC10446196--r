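# Fraud-indicator detectors.
#
# One function per indicator. Per-record detectors take a one-row response
# table and return a single rule result; population detectors take the whole
# table and return one result per record. Every detector is a deterministic,
# pure function of its inputs and parameters, and fires at most once per
# record. Point values follow the study scoring table: 1 point for
# short_completion, geo_simultaneous, cluster, odd_email, speedbump,
# inactive_source, dup_ip and wave; 2 points for cross_form, dup_text,
# tz_disparity and dup_contact. The honeypot is a screener gate, not a scored
# indicator, and reports 0 points.

#' Detector thresholds and parameters
#'
#' @param short_completion_minutes Completion times strictly below this fire
#'   the short-completion rule (minutes, default 8).
#' @param tz_disparity_minutes Client/server disparities strictly above this
#'   fire the time-zone rule (minutes, default 60).
#' @param batch_window_seconds Consecutive submissions closer than this join
#'   one batch in the wave detector (seconds, default 60).
#' @param min_cluster_size Minimum identical/similar-response group size that
#'   fires the cluster rule (default 3).
#' @param similarity_threshold Item-agreement fraction at or above which two
#'   responses count as similar (default 0.90).
#' @param wave_cv_tolerance Maximum coefficient of variation of inter-batch
#'   gaps for batches to count as regularly spaced waves (default 0.10).
#' @param simultaneous_window_seconds Window within which two submissions
#'   count as simultaneous for the county+zip match rule (seconds, default 60).
#' @param email_digit_run Digit-run length in an email local part that counts
#'   as unusual (default 4).
#' @param neardup_text_threshold Normalized edit similarity at or above which
#'   two open-text answers count as near-duplicates (default 0.90).
#' @param email_lexicon Character vector of lower-case given names used by the
#'   misspelling heuristic; defaults to the list shipped in `extdata`.
#' @return An object of class `detector_params`.
#' @export
detector_params <- function(short_completion_minutes = 8,
                            tz_disparity_minutes = 60,
                            batch_window_seconds = 60,
                            min_cluster_size = 3L,
                            similarity_threshold = 0.90,
                            wave_cv_tolerance = 0.10,
                            simultaneous_window_seconds = 60,
                            email_digit_run = 4L,
                            neardup_text_threshold = 0.90,
                            email_lexicon = NULL) {
  p <- list(short_completion_minutes = short_completion_minutes,
            tz_disparity_minutes = tz_disparity_minutes,
            batch_window_seconds = batch_window_seconds,
            min_cluster_size = as.integer(min_cluster_size),
            similarity_threshold = similarity_threshold,
            wave_cv_tolerance = wave_cv_tolerance,
            simultaneous_window_seconds = simultaneous_window_seconds,
            email_digit_run = as.integer(email_digit_run),
            neardup_text_threshold = neardup_text_threshold,
            email_lexicon = email_lexicon %||% default_email_lexicon())
  num <- p[setdiff(names(p), "email_lexicon")]
  if (any(vapply(num, function(v) !is.numeric(v) || v <= 0, logical(1))))
    stop("all detector thresholds must be strictly positive numbers")
  if (p$similarity_threshold > 1 || p$neardup_text_threshold > 1)
    stop("similarity thresholds must be <= 1")
  structure(p, class = "detector_params")
}

#' @export
print.detector_params <- function(x, ...) {
  cat("<detector_params>\n")
  for (nm in setdiff(names(x), "email_lexicon"))
    cat(sprintf("  %-28s %s\n", nm, format(x[[nm]])))
  cat(sprintf("  %-28s %d names\n", "email_lexicon", length(x$email_lexicon)))
  invisible(x)
}

default_email_lexicon <- function() {
  path <- system.file("extdata", "given_names.txt", package = "surveyguard")
  if (!nzchar(path)) return(character())
  tolower(trimws(readLines(path, warn = FALSE)))
}

rule_result <- function(rule_id, fired, points, evidence = "") {
  tibble::new_tibble(list(
    rule_id = rule_id, fired = isTRUE(fired),
    points = if (isTRUE(fired)) as.integer(points) else 0L,
    evidence = as.character(evidence)), nrow = 1L)
}

first_row <- function(r) {
  if (is.data.frame(r)) {
    stopifnot(nrow(r) == 1)
    as.list(r)
  } else as.list(r)
}

# normalization helpers shared by the duplicate detectors
norm_email <- function(x) {
  out <- tolower(trimws(as.character(x)))
  out[is.na(x)] <- ""
  out
}
norm_phone <- function(x) {
  out <- gsub("[^0-9]", "", as.character(x))
  out[is.na(x)] <- ""
  out
}
norm_address <- function(x) {
  out <- tolower(gsub("\\s+", " ", trimws(as.character(x))))
  out[is.na(x)] <- ""
  out
}
norm_open_text <- function(x) {
  out <- tolower(gsub("\\s+", " ", trimws(as.character(x))))
  out <- sub("[[:punct:]]+$", "", out)
  out <- trimws(out)
  out[is.na(x)] <- ""
  out
}

record_ts <- function(r, which) {
  parsed <- paste0(switch(which, client = "client", server = "server",
                          submit = "submit"), "_ts")
  raw <- switch(which, client = "client_timestamp",
                server = "server_timestamp", submit = "submit_instant")
  if (!is.null(r[[parsed]])) r[[parsed]] else parse_ts(r[[raw]])
}

# ---- per-record detectors ---------------------------------------------------

#' Infeasibly short completion time
#'
#' Fires (1 pt) when the completion time is strictly below the threshold;
#' pre-testing of the instrument put valid completion times at 8-20 minutes
#' with a median of 17, so the default threshold is 8 minutes.
#'
#' @param r A one-row response table.
#' @param p [detector_params()].
#' @return A one-row rule-result tibble.
#' @export
detect_short_completion <- function(r, p = detector_params()) {
  r <- first_row(r)
  cm <- r$completion_minutes
  if (is.null(cm) || is.na(cm))
    return(rule_result("short_completion", FALSE, 1L,
                       "completion time missing"))
  rule_result("short_completion", cm < p$short_completion_minutes, 1L,
              sprintf("completion %.3g min (fires < %g min)",
                      cm, p$short_completion_minutes))
}

#' Client/server time-zone disparity
#'
#' Compares the browser-reported timestamp with the server receipt timestamp;
#' a disparity strictly greater than the threshold (default 60 minutes)
#' suggests a respondent outside the target time zone and fires for 2 points.
#' Records without usable timestamp information never fire and are flagged as
#' such.
#'
#' @inheritParams detect_short_completion
#' @return A one-row rule-result tibble.
#' @export
detect_timezone_disparity <- function(r, p = detector_params()) {
  r <- first_row(r)
  ct <- record_ts(r, "client"); st <- record_ts(r, "server")
  if (is.na(ct) || is.na(st))
    return(rule_result("tz_disparity", FALSE, 2L, "no timestamp info"))
  d <- disparity_minutes(ct, st)
  rule_result("tz_disparity", d > p$tz_disparity_minutes, 2L,
              sprintf("client-server disparity %.3g min (fires > %g min)",
                      d, p$tz_disparity_minutes))
}

#' Unusual email format
#'
#' Fires (1 pt) when the local part of the address looks machine-generated:
#' (a) a digit run of length >= `email_digit_run`; (b) a consonant run of
#' length >= 5 after removing digits; or (c) an alphabetic token within edit
#' distance 1-2 of a given-name lexicon entry where the token introduces a
#' doubled letter the name does not have (the "hannaah"/"smiith" misspelling
#' pattern). An address without an `@` fires as malformed.
#'
#' @inheritParams detect_short_completion
#' @return A one-row rule-result tibble; the evidence names the criterion.
#' @export
detect_unusual_email <- function(r, p = detector_params()) {
  r <- first_row(r)
  email <- r$email
  if (is.null(email) || is_blank(email))
    return(rule_result("odd_email", FALSE, 1L, "no email"))
  email <- trimws(email)
  if (!grepl("@", email, fixed = TRUE))
    return(rule_result("odd_email", TRUE, 1L, "malformed"))
  local <- tolower(sub("@.*$", "", email))
  if (grepl(sprintf("[0-9]{%d,}", p$email_digit_run), local))
    return(rule_result("odd_email", TRUE, 1L,
                       sprintf("digit run of %d+ in local part", p$email_digit_run)))
  letters_only <- gsub("[0-9]", "", local)
  runs <- regmatches(letters_only,
                     gregexpr("[bcdfghjklmnpqrstvwxz]+", letters_only))[[1]]
  if (length(runs) && max(nchar(runs)) >= 5)
    return(rule_result("odd_email", TRUE, 1L, "consonant run of 5+"))
  tok <- misspelled_name_token(local, p$email_lexicon)
  if (!is.na(tok))
    return(rule_result("odd_email", TRUE, 1L,
                       sprintf("doubled-letter misspelling of a given name ('%s')", tok)))
  rule_result("odd_email", FALSE, 1L, "no criterion triggered")
}

# A token misspells a lexicon name when it sits at edit distance 1-2 from the
# name AND contains a doubled-letter bigram the name lacks; requiring the new
# doubled letter keeps legitimately doubled names (hannah, emma) from firing
# against close lexicon neighbours.
misspelled_name_token <- function(local, lexicon) {
  if (!length(lexicon)) return(NA_character_)
  tokens <- strsplit(gsub("[^a-z]+", " ", local), " ", fixed = TRUE)[[1]]
  tokens <- tokens[nzchar(tokens)]
  for (tok in tokens) {
    doubles <- unique(regmatches(tok, gregexpr("([a-z])\\1", tok))[[1]])
    if (!length(doubles)) next
    cand <- lexicon[abs(nchar(lexicon) - nchar(tok)) <= 2]
    if (!length(cand)) next
    d <- utils::adist(tok, cand)
    for (nm in cand[d >= 1 & d <= 2]) {
      if (any(!vapply(doubles, grepl, logical(1), x = nm, fixed = TRUE)))
        return(tok)
    }
  }
  NA_character_
}

#' Inactive or nonexistent recruitment source
#'
#' Fires (1 pt) when the reported "how did you hear about us" source was never
#' used at all, or has activity intervals and the submission date falls in
#' none of them. Source strings absent from the calendar are logged but do not
#' fire.
#'
#' @param r A one-row response table.
#' @param cal A [channel_calendar()].
#' @return A one-row rule-result tibble.
#' @export
detect_inactive_source <- function(r, cal) {
  r <- first_row(r)
  src <- r$heard_source
  if (is.null(src) || is_blank(src))
    return(rule_result("inactive_source", FALSE, 1L, "no source reported"))
  src <- trimws(src)
  if (src %in% cal$never_used)
    return(rule_result("inactive_source", TRUE, 1L,
                       sprintf("source '%s' was never used", src)))
  iv <- cal$channels[cal$channels$channel == src, , drop = FALSE]
  if (nrow(iv) == 0) {
    sg_log(sprintf("unknown recruitment source '%s'", src), "debug")
    return(rule_result("inactive_source", FALSE, 1L,
                       sprintf("source '%s' not in calendar", src)))
  }
  ts <- record_ts(r, "submit")
  if (is.na(ts))
    return(rule_result("inactive_source", FALSE, 1L, "no submit timestamp"))
  day <- as.Date(ts, tz = "UTC")
  active <- any(day >= iv$start & day <= iv$end)
  rule_result("inactive_source", !active, 1L,
              sprintf("source '%s' %s on %s", src,
                      if (active) "active" else "inactive", format(day)))
}

#' Incorrect speed-bump answers
#'
#' Speed bumps are questions that require careful reading (e.g. "The man
#' couldn't lift his son because he was so weak. Who was weak?"). Fires (1 pt)
#' when any answered speed-bump item, case-folded and trimmed, is not in its
#' accepted set; a blank answer counts as incorrect. Speed-bump answers live
#' in `sb_<id>` columns; `NA` means the item was not presented.
#'
#' @param r A one-row response table.
#' @param key A [speedbump_key()] covering every answered question id.
#' @return A one-row rule-result tibble.
#' @export
detect_speedbump_failure <- function(r, key) {
  r <- first_row(r)
  sb <- r[grepl("^sb_", names(r))]
  sb <- sb[!vapply(sb, function(v) is.null(v) || is.na(v), logical(1))]
  if (!length(sb))
    return(rule_result("speedbump", FALSE, 1L, "no speed-bump items"))
  unknown <- setdiff(names(sb), names(key))
  if (length(unknown))
    stop("speed-bump question id(s) missing from key: ",
         paste(unknown, collapse = ", "))
  wrong <- vapply(names(sb), function(id) {
    ans <- tolower(trimws(as.character(sb[[id]])))
    !nzchar(ans) || !(ans %in% key[[id]])
  }, logical(1))
  rule_result("speedbump", any(wrong), 1L,
              if (any(wrong))
                paste0("incorrect: ", paste(names(sb)[wrong], collapse = ", "))
              else "all speed bumps correct")
}

#' Cross-form and within-form inconsistency
#'
#' Fires (2 pts) when the survey conflicts with its linked screener or with
#' itself: county or zip mismatch between forms, a zip absent from the
#' reference map, a mismatch between duplicated questions within the survey
#' (item `x` vs item `x_rep`), or a child age implausible for the reported
#' grade. Plausible age for grade g (kindergarten = 0) is g+4 through g+8
#' years, spanning typical US enrollment ages plus one retention year; 5 years
#' old in 8th grade is out of range.
#'
#' @param survey,screener One-row response tables with
#'   `survey$linked_screener_id == screener$record_id`.
#' @param zm A [zip_county_map()].
#' @return A one-row rule-result tibble whose evidence lists every failed
#'   sub-check.
#' @export
detect_cross_form_inconsistency <- function(survey, screener, zm) {
  sv <- first_row(survey); sc <- first_row(screener)
  if (is.null(sv$linked_screener_id) || is.na(sv$linked_screener_id) ||
      sv$linked_screener_id != sc$record_id)
    stop("survey record ", sv$record_id,
         " is not linked to screener record ", sc$record_id)
  fails <- character()
  norm <- function(x) tolower(trimws(as.character(x %||% "")))
  if (!is_blank(sv$counties_marked) && !is_blank(sc$counties_marked) &&
      norm(sv$counties_marked) != norm(sc$counties_marked))
    fails <- c(fails, "county mismatch between forms")
  if (!is_blank(sv$zip) && !is_blank(sc$zip) && norm(sv$zip) != norm(sc$zip))
    fails <- c(fails, "zip mismatch between forms")
  if (!is_blank(sv$zip) && !(trimws(sv$zip) %in% names(zm$entries)))
    fails <- c(fails, sprintf("zip '%s' not in reference map", trimws(sv$zip)))
  rep_items <- grep("^item_.*_rep$", names(sv), value = TRUE)
  for (ri in rep_items) {
    base <- sub("_rep$", "", ri)
    if (!is.null(sv[[base]]) && !is.na(sv[[base]]) && !is.na(sv[[ri]]) &&
        norm(sv[[base]]) != norm(sv[[ri]]))
      fails <- c(fails, sprintf("duplicate-question mismatch (%s)", base))
  }
  age <- sv$child_age_years; grade <- sv$child_grade
  if (!is.null(age) && !is.null(grade) && !is.na(age) && !is.na(grade)) {
    if (age < grade + 4 || age > grade + 8)
      fails <- c(fails, sprintf("age %d implausible for grade %d", age, grade))
  }
  rule_result("cross_form", length(fails) > 0, 2L,
              if (length(fails)) paste(fails, collapse = "; ") else "consistent")
}

#' Honeypot answered
#'
#' The honeypot is a form field invisible to human respondents; any non-blank
#' value signals automation. Reported with 0 points — it is not part of the
#' scoring table — but [screen_eligibility()] treats it as an immediate bar.
#'
#' @param r A one-row response table.
#' @return A one-row rule-result tibble.
#' @export
detect_honeypot <- function(r) {
  r <- first_row(r)
  fired <- !is.null(r$honeypot_value) && !is_blank(r$honeypot_value)
  rule_result("honeypot", fired, 0L,
              if (fired) "honeypot field answered" else "honeypot untouched")
}

# ---- population detectors ---------------------------------------------------

pop_result <- function(rs, rule_id, fired, points, evidence) {
  n <- nrow(rs)
  tibble::new_tibble(list(
    record_id = rs$record_id, rule_id = rep(rule_id, n),
    fired = as.logical(fired),
    points = as.integer(ifelse(fired, points, 0L)),
    evidence = as.character(evidence)), nrow = n)
}

#' Duplicate hashed IP address
#'
#' Every record whose non-empty `ip_hash` occurs at least twice fires (1 pt).
#' Empty hashes never match each other: absent IP logging is not evidence.
#'
#' @param rs A response table.
#' @return A tibble of rule results, one row per record, in input order.
#' @export
detect_duplicate_ip <- function(rs) {
  ip <- trimws(ifelse(is.na(rs$ip_hash), "", rs$ip_hash))
  tab <- table(ip[ip != ""])
  dup <- names(tab)[tab >= 2]
  fired <- ip != "" & ip %in% dup
  pop_result(rs, "dup_ip", fired, 1L,
             ifelse(fired, paste0("ip hash shared (", ip, ")"), ""))
}

#' Duplicate contact details
#'
#' Contact fields are normalized (emails case-folded, phone numbers reduced to
#' digits, addresses case-folded with collapsed whitespace); any record whose
#' normalized non-empty email, phone, or postal address is shared with another
#' record fires (2 pts).
#'
#' @param rs A response table.
#' @return A tibble of rule results, one row per record, in input order.
#' @export
detect_duplicate_contact <- function(rs) {
  dup_of <- function(v) {
    tab <- table(v[v != ""])
    v != "" & v %in% names(tab)[tab >= 2]
  }
  de <- dup_of(norm_email(rs$email))
  dp <- dup_of(norm_phone(rs$phone))
  da <- dup_of(norm_address(rs$postal_address))
  fired <- de | dp | da
  what <- mapply(function(e, p, a)
    paste(c("email", "phone", "address")[c(e, p, a)], collapse = ", "),
    de, dp, da)
  pop_result(rs, "dup_contact", fired, 2L,
             ifelse(fired, paste0("shared contact: ", what), ""))
}

#' Duplicate or near-duplicate open-ended text
#'
#' Optional open-ended answers are normalized (case-folded, whitespace
#' collapsed, terminal punctuation stripped). Records sharing a normalized
#' non-empty text fire (2 pts); pairs whose normalized edit similarity
#' (1 - distance / longer length) reaches the near-duplicate threshold also
#' fire, with "near-duplicate" evidence. Texts shorter than 10 characters
#' after normalization are exempt — short pleasantries collide innocently.
#'
#' @param rs A response table.
#' @param p [detector_params()].
#' @return A tibble of rule results, one row per record, in input order.
#' @export
detect_duplicate_open_text <- function(rs, p = detector_params()) {
  nt <- norm_open_text(rs$open_text)
  eligible <- nchar(nt) >= 10
  tab <- table(nt[eligible])
  exact <- eligible & nt %in% names(tab)[tab >= 2]
  near <- rep(FALSE, nrow(rs))
  u <- unique(nt[eligible])
  if (length(u) >= 2) {
    D <- utils::adist(u, u)
    L <- outer(nchar(u), nchar(u), pmax)
    S <- 1 - D / L
    diag(S) <- 0
    near_u <- u[apply(S >= p$neardup_text_threshold, 1, any)]
    near <- eligible & nt %in% near_u
  }
  fired <- exact | near
  ev <- character(nrow(rs))
  ev[near & !exact] <- "near-duplicate open text"
  ev[exact] <- "open text identical to another respondent"
  pop_result(rs, "dup_text", fired, 2L, ev)
}

#' Simultaneous submissions with matching county and zip
#'
#' Fires (1 pt) for every record sharing an identical (county, zip) pair with
#' at least one other record submitted within the simultaneity window
#' (default 60 s).
#'
#' @param rs A response table.
#' @param p [detector_params()].
#' @return A tibble of rule results, one row per record, in input order.
#' @export
detect_simultaneous_geo_match <- function(rs, p = detector_params()) {
  county <- tolower(trimws(ifelse(is.na(rs$counties_marked), "", rs$counties_marked)))
  zip <- trimws(ifelse(is.na(rs$zip), "", rs$zip))
  key <- paste(county, zip, sep = "|")
  ok <- county != "" & zip != ""
  tt <- as.numeric(if (!is.null(rs$submit_ts)) rs$submit_ts
                   else parse_ts(rs$submit_instant))
  n <- nrow(rs)
  fired <- rep(FALSE, n)
  if (n >= 2) {
    same_geo <- outer(key, key, "==")
    close <- abs(outer(tt, tt, "-")) <= p$simultaneous_window_seconds
    m <- same_geo & close & outer(ok, ok, "&") &
      !is.na(close) & !diag(TRUE, n)
    fired <- apply(m, 1, any)
  }
  pop_result(rs, "geo_simultaneous", fired, 1L,
             ifelse(fired, "same county+zip submitted simultaneously", ""))
}

#' Clusters of identical or similar responses
#'
#' Pairwise similarity between two records is the fraction of `item_*` answers
#' that agree exactly; records are grouped by single linkage at the similarity
#' threshold (connected components of the >=-threshold graph), and every
#' member of a group of at least `min_cluster_size` fires (1 pt).
#'
#' @param rs A response table whose records share a common `item_*` column set.
#' @param p [detector_params()].
#' @return A tibble of rule results, one row per record, in input order.
#' @export
detect_response_cluster <- function(rs, p = detector_params()) {
  n <- nrow(rs)
  icols <- grep("^item_", names(rs), value = TRUE)
  if (n < p$min_cluster_size || !length(icols))
    return(pop_result(rs, "cluster", rep(FALSE, n), 1L, rep("", n)))
  M <- as.matrix(rs[icols])
  M[is.na(M)] <- "missing"
  agree <- matrix(0, n, n)
  for (j in seq_along(icols))
    agree <- agree + outer(M[, j], M[, j], "==")
  S <- agree / length(icols)
  adj <- S >= p$similarity_threshold
  diag(adj) <- FALSE
  comp <- connected_components(adj)
  sizes <- table(comp)
  fired <- as.vector(sizes[as.character(comp)]) >= p$min_cluster_size
  pop_result(rs, "cluster", fired, 1L,
             ifelse(fired, sprintf("member of a similar-response group of %d",
                                   as.vector(sizes[as.character(comp)])), ""))
}

connected_components <- function(adj) {
  n <- nrow(adj)
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cur <- cur + 1L
    queue <- i
    comp[i] <- cur
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      nb <- which(adj[v, ] & is.na(comp))
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Wave-patterned submission timing
#'
#' Detects submissions arriving in batches at regular intervals (e.g. 3
#' responses every 5 minutes). Records are sorted by submission time and
#' partitioned into batches wherever the gap to the previous record exceeds
#' the batch window (default 60 s). If at least three batches have two or
#' more members and the coefficient of variation of the gaps between
#' successive such batch start times is within tolerance (default 0.10),
#' every member of those batches fires (1 pt).
#'
#' @param rs A response table.
#' @param p [detector_params()].
#' @return A tibble of rule results, one row per record, in input order.
#' @export
detect_wave_submission <- function(rs, p = detector_params()) {
  n <- nrow(rs)
  tt <- as.numeric(if (!is.null(rs$submit_ts)) rs$submit_ts
                   else parse_ts(rs$submit_instant))
  fired <- rep(FALSE, n)
  ev <- rep("", n)
  usable <- which(!is.na(tt))
  if (length(usable) >= 2) {
    ord <- usable[order(tt[usable])]
    gaps <- diff(tt[ord])
    batch <- cumsum(c(1, gaps > p$batch_window_seconds))
    starts <- tapply(tt[ord], batch, min)
    sizes <- tapply(tt[ord], batch, length)
    multi <- as.integer(names(sizes)[sizes >= 2])
    if (length(multi) >= 3) {
      g <- diff(starts[as.character(multi)])
      cv <- stats::sd(g) / mean(g)
      if (is.finite(cv) && cv <= p$wave_cv_tolerance) {
        hit <- ord[batch %in% multi]
        fired[hit] <- TRUE
        ev[hit] <- sprintf(
          "batch member; %d regular batches (inter-batch gap CV %.3f)",
          length(multi), cv)
      }
    }
  }
  pop_result(rs, "wave", fired, 1L, ev)
}
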