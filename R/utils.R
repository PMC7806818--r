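# Internal helpers shared across the pipeline.

# Fixed day/month conversion used in every report (claims convention).
DAYS_PER_MONTH <- 30.4375
DAYS_PER_YEAR <- 365.25

#' Parse ISO-8601 dates strictly
#'
#' Returns `NA` for anything that is not a valid `YYYY-MM-DD` date instead of
#' raising, so callers can collect row-level rejects.
#'
#' @param x character vector of dates.
#' @return a `Date` vector with `NA` where parsing failed.
#' @keywords internal
parse_iso_date <- function(x) {
  x <- trimws(as.character(x))
  x[x == ""] <- NA_character_
  out <- as.Date(rep(NA_character_, length(x)))
  ok <- !is.na(x) & grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  out[ok] <- as.Date(x[ok], format = "%Y-%m-%d")
  out
}

days_between <- function(from, to) as.numeric(to - from)

# min() over dates that tolerates NULL/NA pieces; returns NA if nothing left
min_date <- function(...) {
  d <- c(...)
  d <- d[!is.na(d)]
  if (length(d) == 0) return(as.Date(NA))
  min(d)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# root (3-digit or V/E-prefixed) part of an ICD-9 code
icd9_root <- function(code) sub("\\..*$", "", code)

is_valid_icd9 <- function(code) {
  grepl("^[VE]?[0-9]{2,3}(\\.[0-9]{1,2})?$", toupper(trimws(code)))
}

# does `code` fall under `prefix`? A dotted prefix matches by initial string;
# an undotted prefix matches the 3-digit root exactly.
icd9_matches <- function(code, prefix) {
  code <- toupper(trimws(code))
  if (grepl("\\.", prefix)) {
    startsWith(code, prefix)
  } else {
    icd9_root(code) == prefix
  }
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
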