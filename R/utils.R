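# Internal helpers shared across modules. All timestamps in the package are
# naive local clock time represented as POSIXct in the "UTC" zone; daylight
# saving does not exist in this representation.

`%||%` <- function(a, b) if (is.null(a)) b else a

.stopf <- function(fmt, ..., class = "beta2hr_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "beta2hr_error")))
}

#' @keywords internal
.as_naive_time <- function(x) {
  if (inherits(x, "POSIXct")) return(as.POSIXct(as.numeric(x), tz = "UTC",
                                                origin = "1970-01-01"))
  if (inherits(x, "POSIXlt")) return(as.POSIXct(x, tz = "UTC"))
  if (is.character(x) || is.factor(x)) {
    x <- as.character(x)
    out <- as.POSIXct(x, tz = "UTC", format = "%Y-%m-%dT%H:%M:%S")
    miss <- is.na(out) & !is.na(x)
    if (any(miss)) {
      out[miss] <- as.POSIXct(x[miss], tz = "UTC", format = "%Y-%m-%d %H:%M:%S")
    }
    miss <- is.na(out) & !is.na(x)
    if (any(miss)) {
      out[miss] <- as.POSIXct(x[miss], tz = "UTC", format = "%Y-%m-%dT%H:%M")
    }
    return(out)
  }
  .stopf("cannot interpret object of class '%s' as a timestamp", class(x)[1L])
}

# Floor a POSIXct to the whole minute (device bucketing convention).
.floor_minute <- function(t) {
  as.POSIXct(as.numeric(t) - as.numeric(t) %% 60, tz = "UTC",
             origin = "1970-01-01")
}

.naive_date <- function(t) as.Date(t, tz = "UTC")

# Minute of day 0..1439 for minute-aligned POSIXct.
.minute_of_day <- function(t) as.integer((as.numeric(t) %/% 60) %% 1440)

.hour_of_day <- function(t) as.integer((as.numeric(t) %/% 3600) %% 24)

.midnight <- function(date) {
  as.POSIXct(as.numeric(as.Date(date)) * 86400, tz = "UTC",
             origin = "1970-01-01")
}

.fmt_time <- function(t) format(t, "%Y-%m-%dT%H:%M:%S", tz = "UTC")

.is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x >= 0 && x == floor(x)

.is_prob <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x >= 0 && x <= 1
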