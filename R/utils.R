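`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
is_blank <- function(x) {
  is.na(x) | trimws(as.character(x)) == ""
}

log_levels <- c(debug = 1L, info = 2L, warn = 3L)

#' Emit a timestamped log line
#'
#' Logging verbosity is controlled by `options(surveyguard.log_level = )`
#' ("debug", "info" or "warn"; default "info"). Messages below the configured
#' level are suppressed.
#'
#' @param msg Message text.
#' @param level One of "debug", "info", "warn".
#' @return Invisibly, the formatted line (or `NULL` if suppressed).
#' @export
sg_log <- function(msg, level = "info") {
  level <- match.arg(level, names(log_levels))
  threshold <- getOption("surveyguard.log_level", "info")
  if (log_levels[[level]] < log_levels[[threshold]]) return(invisible(NULL))
  line <- sprintf("[%s] %s %s",
                  format(Sys.time(), "%Y-%m-%d %H:%M:%S"), toupper(level), msg)
  message(line)
  invisible(line)
}

# Timestamps travel as ISO 8601 strings with an explicit UTC offset
# ("2022-01-26T12:00:00-0500", "Z" accepted). Strings without an offset carry
# no usable time-zone information and parse to NA: such records are excluded
# from disparity counts rather than erroring, because a missing or mangled
# timestamp is itself evidence.

#' Parse ISO 8601 timestamps with explicit offsets
#'
#' @param x Character vector. Values lacking a `+hhmm`/`-hhmm`/`Z` offset (or
#'   unparseable) yield `NA`.
#' @return POSIXct vector in UTC.
#' @export
parse_ts <- function(x) {
  x <- as.character(x)
  x <- sub(" ", "T", x, fixed = TRUE)
  x <- sub("Z$", "+0000", x)
  x <- sub("([+-]\\d{2}):(\\d{2})$", "\\1\\2", x)
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01", tz = "UTC")
  ok <- !is.na(x) & grepl("[+-][0-9]{4}$", x)
  if (any(ok)) {
    parsed <- strptime(x[ok], "%Y-%m-%dT%H:%M:%S%z", tz = "UTC")
    out[ok] <- as.POSIXct(parsed, tz = "UTC")
  }
  out
}

#' Format timestamps the way the loader expects them
#'
#' @param t POSIXct vector.
#' @return Character vector like `"2022-01-26T12:00:00+0000"`.
#' @export
fmt_ts <- function(t) {
  out <- format(t, "%Y-%m-%dT%H:%M:%S%z", tz = "UTC")
  out[is.na(t)] <- NA_character_
  out
}

#' Absolute client/server timestamp disparity in minutes
#'
#' @param client,server POSIXct vectors.
#' @return Numeric minutes; `NA` where either side is missing.
#' @export
disparity_minutes <- function(client, server) {
  abs(as.numeric(difftime(client, server, units = "mins")))
}
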