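# Shared helpers: rounding, date handling, input checks.

#' Round half away from zero
#'
#' Base `round()` rounds half to even; report tables in this field round
#' half away from zero (so 46.985 prints as 47.0). Used for all percentage
#' and table output formatting.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places.
#' @return numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_up(c(0.125, -0.125), 2)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Classify a raw FAERS date string: "full" (YYYYMMDD), "partial"
# (YYYYMM or YYYY), or "missing".
date_precision <- function(x) {
  x <- trimws(as.character(x))
  out <- rep("missing", length(x))
  ok <- !is.na(x) & x != "" & grepl("^[0-9]+$", x)
  out[ok & nchar(x) %in% c(4L, 6L)] <- "partial"
  out[ok & nchar(x) == 8L] <- "full"
  # 8-digit strings that do not parse as real calendar dates are partial
  full <- out == "full"
  if (any(full)) {
    parsed <- as.Date(x[full], format = "%Y%m%d")
    out[full][is.na(parsed)] <- "partial"
  }
  out
}

# Parse full-precision YYYYMMDD strings to Date; anything else becomes NA.
parse_full_date <- function(x) {
  x <- trimws(as.character(x))
  x[date_precision(x) != "full"] <- NA_character_
  as.Date(x, format = "%Y%m%d")
}

check_fraction <- function(x, name, allow_one = FALSE) {
  hi_ok <- if (allow_one) x <= 1 else x < 1
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || !hi_ok) {
    abort(sprintf("`%s` must be a fraction in [0, %s).", name,
                  if (allow_one) "1]" else "1"),
          class = "faersignal_config_error")
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != as.integer(x)) {
    abort(sprintf("`%s` must be an integer >= %d.", name, min),
          class = "faersignal_config_error")
  }
  invisible(as.integer(x))
}
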