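# internal helpers shared across modules

# completed years between two dates (birthday semantics, not 365.25 division)
age_in_completed_years <- function(dob, on) {
  stopifnot(inherits(dob, "Date"), inherits(on, "Date"))
  dob_lt <- as.POSIXlt(dob)
  on_lt <- as.POSIXlt(on)
  yrs <- on_lt$year - dob_lt$year
  before_birthday <- (on_lt$mon < dob_lt$mon) |
    (on_lt$mon == dob_lt$mon & on_lt$mday < dob_lt$mday)
  yrs - as.integer(before_birthday)
}

# whole calendar days between two Date vectors
days_between <- function(from, to) {
  as.integer(as.Date(to) - as.Date(from))
}

check_proportion <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single proportion in [0, 1].", name),
          class = "matcvrisk_config_error")
  }
  x
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a whole number >= %d.", name, min),
          class = "matcvrisk_config_error")
  }
  as.integer(x)
}

as_date_window <- function(x, name) {
  w <- as.Date(x)
  if (length(w) != 2L || any(is.na(w)) || w[1] >= w[2]) {
    abort(sprintf("`%s` must be two dates with start < end.", name),
          class = "matcvrisk_config_error")
  }
  w
}

# min/max that return a typed NA on empty input (dplyr evaluates summarise
# expressions even for zero-row inputs)
safe_min <- function(x) if (length(x)) min(x) else x[NA_integer_]
safe_max <- function(x) if (length(x)) max(x) else x[NA_integer_]

# stable id formatting
format_ids <- function(prefix, i, width) sprintf(paste0(prefix, "%0", width, "d"), i)

random_times <- function(n) {
  secs <- sample.int(86400L, n, replace = TRUE) - 1L
  sprintf("%02d:%02d:%02d", secs %/% 3600L, (secs %% 3600L) %/% 60L, secs %% 60L)
}
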