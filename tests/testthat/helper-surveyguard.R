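# Shared helpers: small independent oracles and fixture accessors.

# Plain dynamic-programming Levenshtein distance, independent of the
# utils::adist-based path used by the detectors.
lev_dist <- function(a, b) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  prev <- 0:length(b)
  for (i in seq_along(a)) {
    cur <- numeric(length(b) + 1)
    cur[1] <- i
    for (j in seq_along(b)) {
      cur[j + 1] <- min(prev[j + 1] + 1, cur[j] + 1,
                        prev[j] + (a[i] != b[j]))
    }
    prev <- cur
  }
  prev[length(b) + 1]
}

lev_sim <- function(a, b) 1 - lev_dist(a, b) / max(nchar(a), nchar(b))

fixture <- function(...) {
  p <- system.file("extdata", ..., package = "surveyguard")
  if (!nzchar(p)) stop("fixture not found: ", paste(..., collapse = "/"))
  p
}

test_refs <- function(zm) {
  list(zip_map = zm, calendar = default_channel_calendar(),
       speedbump_key = default_speedbump_key())
}

# a tiny two-county map used across detector tests
tiny_map <- function() {
  zip_county_map(c("20601" = "County01", "20602" = "County01",
                   "20606" = "County02"),
                 eligible_counties = c("County01", "County02"))
}

# n clean, mutually independent survey records spread hours apart
clean_surveys <- function(n, t0 = as.POSIXct("2022-02-01 12:00:00",
                                             tz = "UTC")) {
  dplyr::bind_rows(lapply(seq_len(n), function(i) {
    ts <- fmt_ts(t0 + (i - 1) * 7200)
    response_record(
      record_id = sprintf("R%05d", i),
      client_timestamp = ts, server_timestamp = ts, submit_instant = ts,
      zip = c("20601", "20602", "20606")[(i %% 3) + 1],
      counties_marked = c("County01", "County01", "County02")[(i %% 3) + 1],
      email = sprintf("person.%s%02d@example.org", letters[(i %% 20) + 1], i),
      phone = sprintf("410-555-%04d", i),
      postal_address = sprintf("%d Oak St", 100 + i),
      ip_hash = sprintf("hx%06d", i),
      open_text = paste("unique thoughts about schooling number",
                        i, "and such"))
  }))
}
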