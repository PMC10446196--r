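# Labelled synthetic cohorts.
#
# Three respondent archetypes:
#   legitimate    — internally consistent county/zip/age/grade, distinct IPs
#                   and contact details, plausible personal emails, completion
#                   times calibrated to 8-20 min with median 17, zero
#                   client/server disparity, unique free text, daytime arrival
#                   with no two arrivals closer than two minutes.
#   professional  — human survey takers outside the target population:
#                   individually plausible timing and answers, but contact
#                   details duplicated across records and IPs drawn from a
#                   small shared pool.
#   bot           — automated submissions: waves of fixed-size batches at a
#                   regular period, completion times of 1-5 min, digit-heavy
#                   random emails, identical item answers within a wave,
#                   copied open text, a shared county+zip pair, pooled IPs,
#                   wrong speed-bump answers, and a client clock offset of
#                   12 hours (a configurable fraction spoof their clock to
#                   match the server and show zero disparity).
# Fixing the seed makes the generated tables byte-identical across runs.

sim_surnames <- c(
  "smith", "jones", "taylor", "brown", "davis", "wilson", "evans", "walker",
  "white", "green", "wood", "martin", "hughes", "edwards", "turner",
  "parker", "cook", "ward", "morgan", "bailey", "cox", "richards", "gray",
  "james", "mason", "hayes", "ford", "carter", "shaw", "bishop", "dale",
  "page", "reed", "kemp", "lane", "fox", "holmes", "stone", "webb")

sim_streets <- c(
  "Main", "Oak", "Maple", "Cedar", "Park", "Lake", "Hill", "River", "Elm",
  "Walnut", "Chestnut", "Spring", "Meadow", "Forest", "Sunset", "Ridge")

sim_vocab <- c(
  "school", "teacher", "children", "learning", "masks", "classroom", "safety",
  "community", "support", "parents", "testing", "schedule", "transport",
  "lunch", "reading", "math", "recess", "friends", "teachers", "guidance",
  "updates", "communication", "meetings", "homework", "activities", "sports",
  "health", "ventilation", "distance", "virtual", "hybrid", "return",
  "planning", "resources", "staff", "nurses", "cleaning", "protocols",
  "vaccines", "quarantine", "attendance", "grades", "stress", "wellbeing",
  "counselors", "outdoor", "library", "music", "art", "science", "projects",
  "tutoring", "breakfast", "buses", "mornings", "afternoons", "pickup",
  "dropoff", "siblings", "family", "neighbors", "district", "county",
  "policy", "flexibility", "patience", "gratitude", "concerns", "questions",
  "answers", "helpful", "difficult", "improved", "appreciated", "thankful")

bot_text_templates <- c(
  "great survey thanks for the opportunity",
  "very good study i like to participate")

#' Completion-time sampler for legitimate respondents
#'
#' Samples from a scaled Beta(shape, b) distribution on `[min, max]` with `b`
#' solved numerically so the distribution median equals `median`. The
#' calibration targets instrument pre-testing: valid completion times of 8-20
#' minutes with a median of 17. (No triangular distribution on `[8, 20]` can
#' have median 17 — its largest attainable median is about 16.5 — so a Beta
#' family is used instead.)
#'
#' @param n Number of draws.
#' @param min,median,max Distribution support and median, in minutes.
#' @param shape First Beta shape parameter (default 4).
#' @return Numeric vector of completion times, rounded to 3 decimals.
#' @export
rcompletion_minutes <- function(n, min = 8, median = 17, max = 20, shape = 4) {
  stopifnot(min < median, median < max)
  m <- (median - min) / (max - min)
  b <- uniroot(function(b) qbeta(0.5, shape, b) - m,
               c(0.5, 10), extendInt = "downX", tol = 1e-10)$root
  round(min + (max - min) * rbeta(n, shape, b), 3)
}

#' Generate a synthetic zip-to-county map
#'
#' Synthetic counties with disjoint blocks of sequential 5-digit zips; a
#' random subset is marked eligible. Defaults mirror a state with 24 counties
#' of which 8 are study-eligible.
#'
#' @param n_counties Number of counties.
#' @param n_eligible Number of eligible counties (`<= n_counties`).
#' @param seed Integer RNG seed.
#' @param zips_per_county Zips per county block.
#' @return A [zip_county_map()].
#' @export
generate_zip_county_map <- function(n_counties = 24, n_eligible = 8, seed = 1,
                                    zips_per_county = 5) {
  if (n_eligible < 1 || n_eligible > n_counties)
    stop("n_eligible must be between 1 and n_counties")
  set.seed(seed)
  counties <- sprintf("County%02d", seq_len(n_counties))
  zips <- sprintf("%05d", 20600 + seq_len(n_counties * zips_per_county))
  entries <- setNames(rep(counties, each = zips_per_county), zips)
  eligible <- sort(sample(counties, n_eligible))
  zip_county_map(entries, eligible)
}

#' Default synthetic recruitment calendar
#'
#' Four channels active across the whole study window; radio and TV ads are
#' listed as never used (false answer options on the screener).
#'
#' @param start First active date.
#' @param days Length of the window in days.
#' @return A [channel_calendar()].
#' @export
default_channel_calendar <- function(start = as.Date("2022-01-26"),
                                     days = 180) {
  channel_calendar(
    tibble::tibble(
      channel = c("facebook_ad", "community_flyer", "listserv", "postcard"),
      start = start, end = start + days),
    never_used = c("radio_ad", "tv_ad"))
}

#' Default speed-bump answer key
#'
#' Two items: a referent-resolution question ("Who was weak, the man or his
#' son?", accepted answer "the man") and an instructed-response item
#' (accepted answer "strongly agree").
#'
#' @return A [speedbump_key()].
#' @export
default_speedbump_key <- function() {
  speedbump_key(list(sb_weak = "the man", sb_attention = "strongly agree"))
}

#' Simulator configuration
#'
#' @param n_total Cohort size (screener/survey pairs).
#' @param mix Named proportions over `legitimate`, `professional`, `bot`;
#'   must sum to 1.
#' @param seed Integer RNG seed; fixing it makes output byte-identical.
#' @param legit_completion List `min`/`median`/`max` minutes for the
#'   legitimate completion-time calibration (default 8 / 17 / 20).
#' @param bot_completion Length-2 numeric: uniform completion-time range for
#'   bots, minutes (default 1-5).
#' @param bot_wave List `batch_size`, `intra_spacing_s`, `period_s`: bots
#'   submit in batches of `batch_size` spaced `intra_spacing_s` seconds
#'   apart, with batches starting every `period_s` seconds (default 3
#'   responses every 5 minutes, 20 s apart within a batch).
#' @param bot_tz_offset_minutes Client-clock offset of non-spoofing bots
#'   (default 720, i.e. 12 time zones away).
#' @param bot_spoof_fraction Fraction of bots that set their client clock to
#'   match the server and therefore show zero disparity (default 0.2).
#' @param ip_pool List `professional`/`bot`: shared IP-pool sizes.
#' @param start POSIXct study start; the bot burst begins here, human
#'   traffic starts 11.5 h later.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_total = 300,
                          mix = c(legitimate = 0.7, professional = 0.1,
                                  bot = 0.2),
                          seed = 1L,
                          legit_completion = list(min = 8, median = 17,
                                                  max = 20),
                          bot_completion = c(1, 5),
                          bot_wave = list(batch_size = 3L,
                                          intra_spacing_s = 20,
                                          period_s = 300),
                          bot_tz_offset_minutes = 720,
                          bot_spoof_fraction = 0.2,
                          ip_pool = list(professional = 2L, bot = 4L),
                          start = as.POSIXct("2022-01-27 00:30:00",
                                             tz = "UTC")) {
  if (is.null(names(mix)))
    names(mix) <- c("legitimate", "professional", "bot")
  mix <- mix[c("legitimate", "professional", "bot")]
  if (anyNA(mix) || any(mix < 0) || any(mix > 1) ||
      abs(sum(mix) - 1) > 1e-8)
    stop("mix must be proportions over legitimate/professional/bot summing to 1")
  if (n_total < 0) stop("n_total must be >= 0")
  structure(list(n_total = as.integer(n_total), mix = mix,
                 seed = as.integer(seed), legit_completion = legit_completion,
                 bot_completion = bot_completion, bot_wave = bot_wave,
                 bot_tz_offset_minutes = bot_tz_offset_minutes,
                 bot_spoof_fraction = bot_spoof_fraction,
                 ip_pool = ip_pool, start = start),
            class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf("<cohort_config> n=%d seed=%d mix: legit %.2f / pro %.2f / bot %.2f\n",
              x$n_total, x$seed, x$mix[["legitimate"]],
              x$mix[["professional"]], x$mix[["bot"]]))
  invisible(x)
}

# largest-remainder apportionment of n_total over the mixture
mix_counts <- function(n, mix) {
  raw <- n * mix
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Generate a labelled synthetic cohort
#'
#' Produces paired screener and survey tables plus a ground-truth label per
#' survey record. See the module header comments and the methods vignette
#' for what each archetype emulates.
#'
#' @param cfg A [cohort_config()].
#' @param zm A [zip_county_map()] to sample counties and zips from.
#' @return A list with `screeners`, `surveys` (both `response_tbl`) and
#'   `labels` (tibble `record_id`, `archetype`).
#' @export
generate_cohort <- function(cfg, zm) {
  stopifnot(inherits(cfg, "cohort_config"), inherits(zm, "zip_county_map"))
  set.seed(cfg$seed)
  counts <- mix_counts(cfg$n_total, cfg$mix)
  n_leg <- counts[[1]]; n_pro <- counts[[2]]; n_bot <- counts[[3]]
  n_hum <- n_leg + n_pro

  elig_zips <- names(zm$entries)[zm$entries %in% zm$eligible_counties]
  if (!length(elig_zips)) stop("zip map has no eligible zips")
  lexicon <- default_email_lexicon()
  if (!length(lexicon)) lexicon <- c("jane", "john", "maria", "david")

  hum <- if (n_hum > 0) {
    arch <- sample(c(rep("legitimate", n_leg), rep("professional", n_pro)))
    tt <- cfg$start + 11.5 * 3600 + cumsum(runif(n_hum, 120, 3600))
    zip <- sample(elig_zips, n_hum, replace = TRUE)
    first <- sample(lexicon, n_hum, replace = TRUE)
    last <- sample(sim_surnames, n_hum, replace = TRUE)
    email <- paste0(first, ".", last, sprintf("%02d", sample(0:99, n_hum, TRUE)),
                    "@", sample(c("example.org", "mailbox.net", "inbox.co"),
                                n_hum, TRUE))
    for (it in 1:50) {
      d <- duplicated(email)
      if (!any(d)) break
      email[d] <- paste0(first[d], ".", last[d],
                         sprintf("%02d", sample(0:99, sum(d), TRUE)),
                         "@", sample(c("example.org", "mailbox.net", "inbox.co"),
                                     sum(d), TRUE))
    }
    digits <- sample(0:9999999, n_hum)
    grade <- sample(0:8, n_hum, replace = TRUE)
    item_vals <- matrix(sample(c("a", "b", "c", "d"), n_hum * 20, TRUE),
                        nrow = n_hum)
    dup_val <- sample(c("yes", "no"), n_hum, replace = TRUE)
    list(
      archetype = arch,
      submit = tt,
      client_off_min = rep(0, n_hum),
      completion = rcompletion_minutes(n_hum,
                                       min = cfg$legit_completion$min,
                                       median = cfg$legit_completion$median,
                                       max = cfg$legit_completion$max),
      county = unname(zm$entries[zip]),
      zip = zip,
      heard = sample(c("facebook_ad", "community_flyer", "listserv",
                       "postcard"), n_hum, TRUE),
      email = email,
      phone = sprintf("410-%03d-%04d", digits %/% 10000, digits %% 10000),
      address = sprintf("%d %s St", 100 + seq_len(n_hum),
                        sample(sim_streets, n_hum, TRUE)),
      ip = sprintf("h%08x", sample.int(.Machine$integer.max, n_hum)),
      grade = grade,
      age = grade + sample(5:7, n_hum, replace = TRUE),
      items = item_vals,
      dup_val = dup_val,
      open_text = vapply(seq_len(n_hum), function(i)
        paste(sample(sim_vocab, 9), collapse = " "), character(1)),
      sb_weak = rep("the man", n_hum),
      sb_attention = rep("strongly agree", n_hum))
  }

  # professionals: duplicate contact details in groups of two (a trailing
  # singleton joins the previous group) and pooled IPs
  if (n_hum > 0 && n_pro > 0) {
    pro_idx <- which(hum$archetype == "professional")
    if (length(pro_idx) >= 2) {
      grp <- ceiling(seq_along(pro_idx) / 2)
      if (sum(grp == max(grp)) == 1 && max(grp) > 1)
        grp[grp == max(grp)] <- max(grp) - 1
      for (g in unique(grp)) {
        members <- pro_idx[grp == g]
        hum$email[members] <- hum$email[members[1]]
        hum$phone[members] <- hum$phone[members[1]]
      }
    }
    pool <- sprintf("p%07x", sample.int(.Machine$integer.max,
                                        cfg$ip_pool$professional))
    hum$ip[pro_idx] <- sample(pool, length(pro_idx), replace = TRUE)
  }

  bot <- if (n_bot > 0) {
    bw <- cfg$bot_wave
    k <- seq_len(n_bot) - 1
    tt <- cfg$start + (k %/% bw$batch_size) * bw$period_s +
      (k %% bw$batch_size) * bw$intra_spacing_s
    spoof <- runif(n_bot) < cfg$bot_spoof_fraction
    pair_zip <- sample(elig_zips, 1)
    wave_id <- k %/% bw$batch_size
    wave_answers <- matrix(sample(c("a", "b", "c", "d"),
                                  (max(wave_id) + 1) * 20, TRUE),
                           nrow = max(wave_id) + 1)
    grade <- sample(0:8, n_bot, replace = TRUE)
    pool <- sprintf("b%07x", sample.int(.Machine$integer.max,
                                        cfg$ip_pool$bot))
    dup_val <- sample(c("yes", "no"), n_bot, replace = TRUE)
    list(
      archetype = rep("bot", n_bot),
      submit = tt,
      client_off_min = ifelse(spoof, 0, cfg$bot_tz_offset_minutes),
      completion = round(runif(n_bot, cfg$bot_completion[1],
                               cfg$bot_completion[2]), 3),
      county = rep(unname(zm$entries[[pair_zip]]), n_bot),
      zip = rep(pair_zip, n_bot),
      heard = rep("facebook_ad", n_bot),
      email = paste0(
        vapply(seq_len(n_bot), function(i)
          paste(sample(letters, 6, TRUE), collapse = ""), character(1)),
        sprintf("%06d", sample(0:999999, n_bot, TRUE)), "@mail.com"),
      phone = sprintf("443-%03d-%04d",
                      sample(0:999, n_bot, TRUE), sample(0:9999, n_bot, TRUE)),
      address = sprintf("%d %s Ave", sample(1:99, n_bot, TRUE),
                        sample(sim_streets, n_bot, TRUE)),
      ip = sample(pool, n_bot, replace = TRUE),
      grade = grade,
      age = grade + 6L,
      items = wave_answers[wave_id + 1, , drop = FALSE],
      dup_val = dup_val,
      open_text = sample(bot_text_templates, n_bot, replace = TRUE),
      sb_weak = rep("his son", n_bot),
      sb_attention = rep("agree", n_bot))
  }

  fields <- c("archetype", "submit", "client_off_min", "completion", "county",
              "zip", "heard", "email", "phone", "address", "ip", "grade",
              "age", "dup_val", "open_text", "sb_weak", "sb_attention")
  comb <- lapply(fields, function(f) c(if (!is.null(hum)) hum[[f]],
                                       if (!is.null(bot)) bot[[f]]))
  names(comb) <- fields
  items <- rbind(if (!is.null(hum)) hum$items, if (!is.null(bot)) bot$items)
  n <- length(comb$archetype)

  if (n == 0) {
    empty <- as_response_tbl(tibble::tibble(record_id = character(),
                                            form = character()))
    return(list(screeners = empty, surveys = empty,
                labels = tibble::tibble(record_id = character(),
                                        archetype = character())))
  }

  ord <- order(comb$submit)
  comb <- lapply(comb, function(v) v[ord])
  items <- items[ord, , drop = FALSE]
  comb$submit <- as.POSIXct(comb$submit[seq_len(n)], origin = "1970-01-01",
                            tz = "UTC")

  scr_id <- sprintf("S%05d", seq_len(n))
  sur_id <- sprintf("R%05d", seq_len(n))
  sur_server <- comb$submit
  sur_client <- sur_server - comb$client_off_min * 60
  scr_server <- sur_server - comb$completion * 60 - 120
  scr_client <- scr_server - comb$client_off_min * 60
  scr_completion <- round(runif(n, 1, 3), 3)

  base <- tibble::tibble(
    counties_marked = comb$county, zip = comb$zip,
    heard_source = comb$heard, captcha_passed = TRUE, honeypot_value = "",
    email = comb$email, phone = comb$phone, postal_address = comb$address,
    ip_hash = comb$ip, child_age_years = as.integer(comb$age),
    child_grade = as.integer(comb$grade),
    sb_weak = comb$sb_weak, sb_attention = comb$sb_attention)

  screeners <- dplyr::bind_cols(
    tibble::tibble(record_id = scr_id, form = "screener",
                   linked_screener_id = NA_character_,
                   client_timestamp = fmt_ts(scr_client),
                   server_timestamp = fmt_ts(scr_server),
                   submit_instant = fmt_ts(scr_server),
                   completion_minutes = scr_completion),
    base, tibble::tibble(open_text = ""))

  item_tbl <- tibble::as_tibble(as.data.frame(items,
                                              stringsAsFactors = FALSE))
  names(item_tbl) <- sprintf("item_%02d", seq_len(ncol(items)))
  surveys <- dplyr::bind_cols(
    tibble::tibble(record_id = sur_id, form = "survey",
                   linked_screener_id = scr_id,
                   client_timestamp = fmt_ts(sur_client),
                   server_timestamp = fmt_ts(sur_server),
                   submit_instant = fmt_ts(sur_server),
                   completion_minutes = comb$completion),
    base, tibble::tibble(open_text = comb$open_text),
    item_tbl,
    tibble::tibble(item_dupcheck = comb$dup_val,
                   item_dupcheck_rep = comb$dup_val))

  list(screeners = as_response_tbl(screeners),
       surveys = as_response_tbl(surveys),
       labels = tibble::tibble(record_id = sur_id,
                               archetype = comb$archetype))
}

#' Generate a brute-force screener probe stream
#'
#' Emulates an attacker repeatedly probing the public eligibility screener
#' with county x zip combinations to discover one that passes validation.
#' Attempts cycle through a shuffled enumeration of all combinations in rapid
#' succession (2 s apart); once a combination passing the zip-county check is
#' hit, every subsequent attempt reuses it.
#'
#' @param n_attempts Number of screener attempts (>= 1).
#' @param seed Integer RNG seed.
#' @param zm A [zip_county_map()].
#' @return A `response_tbl` of screener records.
#' @export
generate_bruteforce_probe_stream <- function(n_attempts, seed, zm) {
  stopifnot(n_attempts >= 1)
  set.seed(seed)
  counties <- unique(unname(zm$entries))
  zips <- names(zm$entries)
  combos <- expand.grid(county = counties, zip = zips,
                        stringsAsFactors = FALSE)
  combos <- combos[sample.int(nrow(combos)), , drop = FALSE]
  county <- character(n_attempts); zip <- character(n_attempts)
  found <- NULL
  for (i in seq_len(n_attempts)) {
    if (is.null(found)) {
      j <- ((i - 1) %% nrow(combos)) + 1
      county[i] <- combos$county[j]; zip[i] <- combos$zip[j]
      if (zm$entries[[zip[i]]] == county[i] &&
          county[i] %in% zm$eligible_counties)
        found <- c(county[i], zip[i])
    } else {
      county[i] <- found[1]; zip[i] <- found[2]
    }
  }
  start <- as.POSIXct("2022-01-27 03:00:00", tz = "UTC")
  tt <- start + (seq_len(n_attempts) - 1) * 2
  as_response_tbl(tibble::tibble(
    record_id = sprintf("P%05d", seq_len(n_attempts)),
    form = "screener", linked_screener_id = NA_character_,
    client_timestamp = fmt_ts(tt), server_timestamp = fmt_ts(tt),
    submit_instant = fmt_ts(tt),
    completion_minutes = 0.1,
    counties_marked = county, zip = zip, heard_source = "facebook_ad",
    captcha_passed = TRUE, honeypot_value = "",
    email = sprintf("probe%05d@mail.com", seq_len(n_attempts)),
    phone = "", postal_address = "", ip_hash = "",
    child_age_years = 10L, child_grade = 5L, open_text = "",
    sb_weak = "the man", sb_attention = "strongly agree"))
}
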