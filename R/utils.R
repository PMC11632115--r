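# Internal helpers shared across modules.

# FAERS partial dates are digit strings: YYYY, YYYYMM or YYYYMMDD.
is_partial_date <- function(x) {
  !is.na(x) & grepl("^[0-9]{4}([0-9]{2}([0-9]{2})?)?$", x)
}

is_full_date <- function(x) {
  !is.na(x) & grepl("^[0-9]{8}$", x)
}

# Parse an 8-digit date string to Date; NA when the calendar rejects it
# (e.g. 20190230).
parse_full_date <- function(x) {
  d <- as.Date(rep(NA_character_, length(x)))
  ok <- is_full_date(x)
  d[ok] <- as.Date(x[ok], format = "%Y%m%d")
  d
}

# Round half away from zero at `digits` decimals (commercial rounding, as used
# for printed percentages; base round() is half-to-even). The epsilon guards
# values whose decimal literal sits a representation error below the midpoint.
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# Format a number at <= 2 decimals, trailing zeros trimmed: 2.5, 0.77, 8.1, 1.
fmt_num2 <- function(x) {
  out <- sprintf("%.2f", round_half_up(x, 2))
  out <- sub("0+$", "", out)
  out <- sub("\\.$", "", out)
  out[is.na(x)] <- NA_character_
  out
}

fmt_est_ci <- function(est, lo, hi) {
  out <- sprintf("%s (%s, %s)", fmt_num2(est), fmt_num2(lo), fmt_num2(hi))
  out[is.na(est)] <- NA_character_
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
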