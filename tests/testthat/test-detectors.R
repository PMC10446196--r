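p <- detector_params()

test_that("short-completion fires strictly below the threshold", {
  cases <- list(list(7, TRUE), list(8, FALSE), list(17, FALSE),
                list(7.999, TRUE), list(8.001, FALSE))
  for (cs in cases) {
    res <- detect_short_completion(response_record(completion_minutes = cs[[1]]), p)
    expect_equal(res$fired, cs[[2]], info = paste(cs[[1]], "min"))
    expect_equal(res$points, if (cs[[2]]) 1L else 0L)
  }
  miss <- detect_short_completion(response_record(completion_minutes = NA), p)
  expect_false(miss$fired)
  expect_match(miss$evidence, "missing")
})

test_that("time-zone disparity fires strictly above the threshold", {
  at <- function(mins) {
    base <- as.POSIXct("2022-02-01 12:00:00", tz = "UTC")
    response_record(server_timestamp = fmt_ts(base),
                    client_timestamp = fmt_ts(base - mins * 60))
  }
  for (cs in list(list(180, TRUE), list(60, FALSE), list(0, FALSE),
                  list(60.5, TRUE), list(59.9, FALSE))) {
    res <- detect_timezone_disparity(at(cs[[1]]), p)
    expect_equal(res$fired, cs[[2]], info = paste(cs[[1]], "min"))
    expect_equal(res$points, if (cs[[2]]) 2L else 0L)
  }
  nt <- detect_timezone_disparity(
    response_record(client_timestamp = "2022-02-01 12:00:00"), p)
  expect_false(nt$fired)
  expect_match(nt$evidence, "no timestamp info")
})

test_that("duplicate IP hashes fire for every sharer; empty hashes never match", {
  rs <- clean_surveys(3)
  rs$ip_hash <- c("A", "A", "B")
  expect_equal(detect_duplicate_ip(rs)$fired, c(TRUE, TRUE, FALSE))
  rs$ip_hash <- c("A", "B", "C")
  expect_false(any(detect_duplicate_ip(rs)$fired))
  rs$ip_hash <- c("", "", "B")
  expect_false(any(detect_duplicate_ip(rs)$fired))
})

test_that("duplicate contact details are matched after normalization", {
  rs <- clean_surveys(3)
  rs$email <- c("A@x.com", "a@X.com", "c@x.com")
  res <- detect_duplicate_contact(rs)
  expect_equal(res$fired, c(TRUE, TRUE, FALSE))
  expect_equal(res$points[1], 2L)

  rs <- clean_surveys(2)
  rs$phone <- c("(410) 555-0101", "4105550101")
  res <- detect_duplicate_contact(rs)
  expect_true(all(res$fired))
  # the oracle for phone normalization: strip every non-digit
  expect_equal(gsub("[^0-9]", "", rs$phone[1]),
               gsub("[^0-9]", "", rs$phone[2]))

  rs <- clean_surveys(2)
  rs$email <- rs$phone <- rs$postal_address <- c("", "")
  expect_false(any(detect_duplicate_contact(rs)$fired))
})

test_that("unusual email heuristics catch the documented patterns", {
  fires <- function(e) detect_unusual_email(response_record(email = e), p)
  expect_true(fires("asfs241421@email.com")$fired)         # digit run
  expect_true(fires("hannaahsmiithweka3242@email.com")$fired)
  expect_true(fires("xkcdqrstv@email.com")$fired)          # consonant run
  expect_true(fires("hannaah@email.com")$fired)            # doubled misspelling
  expect_match(fires("hannaah@email.com")$evidence, "misspelling")
  expect_true(fires("no-at-sign")$fired)
  expect_match(fires("no-at-sign")$evidence, "malformed")
  expect_false(fires("jane.smith@gmail.com")$fired)
  expect_false(fires("hannah.smith@gmail.com")$fired)      # real doubled name
  # the packaged calibration list of plausible addresses never fires
  legit <- readLines(fixture("legit_emails.txt"))
  expect_length(legit, 50)
  fired <- vapply(legit, function(e) fires(e)$fired, logical(1))
  expect_equal(sum(fired), 0)
})

test_that("inactive or nonexistent recruitment sources fire", {
  cal <- channel_calendar(
    tibble::tibble(channel = c("facebook_ad", "community_flyer"),
                   start = as.Date(c("2022-01-01", "2022-01-01")),
                   end = as.Date(c("2022-01-15", "2022-12-31"))),
    never_used = "radio_ad")
  at <- function(src, day) response_record(
    heard_source = src,
    submit_instant = paste0(day, "T12:00:00+0000"))
  expect_true(detect_inactive_source(at("facebook_ad", "2022-02-01"), cal)$fired)
  expect_false(detect_inactive_source(at("facebook_ad", "2022-01-10"), cal)$fired)
  expect_true(detect_inactive_source(at("radio_ad", "2022-01-10"), cal)$fired)
  expect_false(detect_inactive_source(at("community_flyer", "2022-06-01"), cal)$fired)
  expect_false(detect_inactive_source(at("word of mouth", "2022-06-01"), cal)$fired)
})

test_that("speed-bump answers are matched case-insensitively; blanks fail", {
  key <- default_speedbump_key()
  at <- function(ans) response_record(sb_weak = ans,
                                      sb_attention = "Strongly Agree")
  expect_false(detect_speedbump_failure(at("the man"), key)$fired)
  expect_false(detect_speedbump_failure(at("  The MAN "), key)$fired)
  expect_true(detect_speedbump_failure(at("his son"), key)$fired)
  expect_true(detect_speedbump_failure(at(""), key)$fired)
  expect_error(
    detect_speedbump_failure(response_record(sb_mystery = "x"), key),
    "sb_mystery")
  none <- detect_speedbump_failure(response_record(), key)
  expect_false(none$fired)
})

test_that("cross-form inconsistencies fire on any failed sub-check", {
  zm <- tiny_map()
  scr <- response_record(record_id = "S1", form = "screener")
  sv <- function(...) response_record(linked_screener_id = "S1", ...)
  # child age implausible for grade: 5 years old in 8th grade
  expect_true(detect_cross_form_inconsistency(
    sv(child_age_years = 5, child_grade = 8), scr, zm)$fired)
  # nonexistent zip
  res <- detect_cross_form_inconsistency(sv(zip = "00000"), scr, zm)
  expect_true(res$fired)
  expect_match(res$evidence, "00000")
  # consistent forms, age 13 in grade 8 (within grade+4 .. grade+8)
  expect_false(detect_cross_form_inconsistency(
    sv(child_age_years = 13, child_grade = 8), scr, zm)$fired)
  # kindergarten bounds: ages 4-8 plausible for grade 0
  expect_false(detect_cross_form_inconsistency(
    sv(child_age_years = 4, child_grade = 0), scr, zm)$fired)
  expect_true(detect_cross_form_inconsistency(
    sv(child_age_years = 9, child_grade = 0), scr, zm)$fired)
  # county mismatch between forms; evidence lists every failure
  res <- detect_cross_form_inconsistency(
    sv(counties_marked = "County02", zip = "00000"), scr, zm)
  expect_true(res$fired)
  expect_match(res$evidence, "county mismatch")
  expect_match(res$evidence, "not in reference map")
  # duplicate questions within the survey
  expect_true(detect_cross_form_inconsistency(
    sv(item_dup = "yes", item_dup_rep = "no"), scr, zm)$fired)
  expect_error(detect_cross_form_inconsistency(
    response_record(linked_screener_id = "S9"), scr, zm), "not linked")
})

test_that("duplicate and near-duplicate open text fires; short texts exempt", {
  rs <- clean_surveys(3)
  rs$open_text <- c("Thanks for this survey!", "thanks for this  survey",
                    "totally different words here")
  res <- detect_duplicate_open_text(rs, p)
  expect_equal(res$fired, c(TRUE, TRUE, FALSE))
  expect_equal(res$points[1], 2L)

  rs$open_text <- c("the schools did great", "the school did great",
                    "unrelated commentary entirely")
  sim <- lev_sim(rs$open_text[1], rs$open_text[2])
  expect_gte(sim, p$neardup_text_threshold)  # oracle agrees it is a near-dup
  res <- detect_duplicate_open_text(rs, p)
  expect_equal(res$fired, c(TRUE, TRUE, FALSE))
  expect_match(res$evidence[1], "near-duplicate")

  rs$open_text <- c("", "", "")
  expect_false(any(detect_duplicate_open_text(rs, p)$fired))
  rs$open_text <- c("ok", "ok", "ok")  # < 10 chars after normalization
  expect_false(any(detect_duplicate_open_text(rs, p)$fired))
})

test_that("simultaneous county+zip matches respect the time window", {
  base <- as.POSIXct("2022-02-01 12:00:00", tz = "UTC")
  mk <- function(gap_s, zip2 = "20601") {
    rs <- clean_surveys(2)
    rs$counties_marked <- c("County01", "County01")
    rs$zip <- c("20601", zip2)
    rs$submit_instant <- fmt_ts(c(base, base + gap_s))
    as_response_tbl(rs[setdiff(names(rs), surveyguard:::derived_columns)])
  }
  expect_true(all(detect_simultaneous_geo_match(mk(30), p)$fired))
  expect_false(any(detect_simultaneous_geo_match(mk(7200), p)$fired))
  expect_false(any(detect_simultaneous_geo_match(mk(30, zip2 = "20602"), p)$fired))
})

test_that("response clusters need 3+ members at the similarity threshold", {
  mk <- function(vecs) {
    rs <- clean_surveys(length(vecs))
    items <- do.call(rbind, vecs)
    colnames(items) <- sprintf("item_%02d", seq_len(ncol(items)))
    dplyr::bind_cols(rs[setdiff(names(rs), colnames(items))],
                     tibble::as_tibble(as.data.frame(items)))
  }
  v <- rep("a", 20)
  expect_true(all(detect_response_cluster(mk(list(v, v, v)), p)$fired))
  expect_false(any(detect_response_cluster(mk(list(v, v)), p)$fired))
  # three vectors pairwise agreeing on 19/20 items (0.95 >= 0.90)
  v2 <- v; v2[20] <- "b"
  v3 <- v; v3[20] <- "c"
  vecs <- list(v, v2, v3)
  # brute-force similarity oracle
  for (i in 1:2) for (j in (i + 1):3)
    expect_gte(mean(vecs[[i]] == vecs[[j]]), p$similarity_threshold)
  expect_true(all(detect_response_cluster(mk(vecs), p)$fired))
  # dissimilar background records stay out of the group
  w <- rep(c("x", "y"), 10)
  res <- detect_response_cluster(mk(list(v, v, v, w)), p)
  expect_equal(res$fired, c(TRUE, TRUE, TRUE, FALSE))
})

test_that("wave submissions fire on regular batches and not on sparse arrivals", {
  base <- as.POSIXct("2022-02-01 02:00:00", tz = "UTC")
  mk <- function(times) {
    rs <- clean_surveys(length(times))
    rs$submit_instant <- fmt_ts(base + times)
    as_response_tbl(rs[setdiff(names(rs), surveyguard:::derived_columns)])
  }
  # 3 responses every 5 minutes, 20 s apart within a batch
  times <- as.vector(outer(c(0, 20, 40), c(0, 300, 600), "+"))
  expect_true(all(detect_wave_submission(mk(times), p)$fired))
  expect_false(any(detect_wave_submission(mk(0), p)$fired))

  # 30 arrivals uniform over 24 h: check the detector against a brute-force
  # batching oracle computed right here
  set.seed(202)
  tt <- sort(runif(30, 0, 86400))
  gaps <- diff(tt)
  batch <- cumsum(c(1, gaps > p$batch_window_seconds))
  sizes <- table(batch)
  multi <- names(sizes)[sizes >= 2]
  oracle_fires <- FALSE
  if (length(multi) >= 3) {
    starts <- tapply(tt, batch, min)[multi]
    cv <- sd(diff(starts)) / mean(diff(starts))
    oracle_fires <- is.finite(cv) && cv <= p$wave_cv_tolerance
  }
  res <- detect_wave_submission(mk(tt), p)
  expect_equal(any(res$fired), oracle_fires)
  expect_false(oracle_fires)  # sparse random arrivals are not waves
})

test_that("honeypot fires only on non-blank values", {
  expect_false(detect_honeypot(response_record(honeypot_value = ""))$fired)
  expect_false(detect_honeypot(response_record(honeypot_value = "  "))$fired)
  res <- detect_honeypot(response_record(honeypot_value = "yes"))
  expect_true(res$fired)
  expect_equal(res$points, 0L)  # screener gate, not a scored indicator
})

test_that("population detectors are order-invariant and deterministic", {
  zm <- generate_zip_county_map(6, 3, seed = 9)
  coh <- generate_cohort(cohort_config(n_total = 40, seed = 9), zm)
  rs <- coh$surveys
  set.seed(31)
  perm <- sample(nrow(rs))
  detectors <- list(
    dup_ip = detect_duplicate_ip,
    dup_contact = detect_duplicate_contact,
    dup_text = function(x) detect_duplicate_open_text(x, p),
    geo = function(x) detect_simultaneous_geo_match(x, p),
    cluster = function(x) detect_response_cluster(x, p),
    wave = function(x) detect_wave_submission(x, p))
  for (nm in names(detectors)) {
    f <- detectors[[nm]]
    a <- f(rs)
    b <- f(rs[perm, ])
    b <- b[match(a$record_id, b$record_id), ]
    expect_equal(b$fired, a$fired, info = nm)
    expect_identical(f(rs)$fired, a$fired, info = paste(nm, "determinism"))
  }
})
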