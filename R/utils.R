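#' @keywords internal
"_PACKAGE"

# Condition helpers: every user-facing failure is a classed condition so
# callers (and tests) can distinguish schema errors from engine errors etc.
dq_abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "dq_error")))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

is_null_value <- function(x) is.na(x) | x == ""

# Strict decimal-number recognition on raw strings ("65", "-3.2", "0.74");
# scientific notation and stray whitespace are treated as malformed.
parses_numeric <- function(x) {
  !is.na(x) & grepl("^-?[0-9]+(\\.[0-9]+)?$", x)
}

as_num <- function(x) suppressWarnings(as.numeric(x))

# A YYYYMMDD string parses iff it is exactly 8 digits, is a real calendar
# date (month 1-12, real day-of-month, leap years), and its year falls in
# [min_year, max_year]. Returns a logical vector; NA input -> FALSE.
parses_date8 <- function(x, min_year = 1900, max_year = 2100) {
  ok <- !is.na(x) & grepl("^[0-9]{8}$", x)
  out <- rep(FALSE, length(x))
  if (any(ok)) {
    d <- as.Date(x[ok], format = "%Y%m%d")
    yr <- as_num(substr(x[ok], 1, 4))
    out[ok] <- !is.na(d) & yr >= min_year & yr <= max_year
  }
  out
}

# Numeric day count for comparing YYYYMMDD strings; NA when unparseable.
date8_value <- function(x) {
  d <- rep(NA_real_, length(x))
  ok <- parses_date8(x)
  if (any(ok)) d[ok] <- as.numeric(as.Date(x[ok], format = "%Y%m%d"))
  d
}
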