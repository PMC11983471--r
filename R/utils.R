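# shared internal helpers

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Round half away from zero
#'
#' Commercial ("half-up") rounding to a fixed number of decimals. Unlike
#' [base::round()], which rounds half to even, `round_half_up(0.695, 2)` is
#' `0.70`. Used for all reported percentages and odds-ratio tables.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_up(0.695, 2)   # 0.70
#' round(0.695, 2)           # 0.69 (banker's rounding)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # the 1e-8 guard absorbs binary representation error in x * p (values here
  # are percentages / odds ratios, magnitude << 1e6, so the guard is safe)
  sign(x) * trunc(abs(x) * p + 0.5 + 1e-8) / p
}

# collapse internal whitespace and trim
squish <- function(x) gsub("[[:space:]]+", " ", trimws(x))

# trailing tokens stripped from verbatim drug names before dictionary lookup
default_dose_suffixes <- function() {
  c("[0-9]+(\\.[0-9]+)?[[:space:]]*(mg|mcg|g|ml|iu|units?)",
    "tablets?", "capsules?", "caps", "injection", "solution", "oral",
    "er", "xr", "cr", "hfa")
}

#' Normalize a verbatim drug-name string to a dictionary key
#'
#' Lowercases, trims, collapses internal whitespace and repeatedly strips
#' trailing dosage/form tokens (e.g. `"40MG"`, `"tablets"`). This is the key
#' normalization applied to both dictionary entries and incoming names.
#'
#' @param x character vector of verbatim names.
#' @param suffixes regular expressions for trailing tokens to strip; each is
#'   matched as a whole space-separated trailing token.
#' @return normalized character vector.
#' @export
#' @examples
#' norm_key("HUMIRA  40MG")  # "humira"
norm_key <- function(x, suffixes = default_dose_suffixes()) {
  x <- tolower(squish(x))
  pat <- paste0("[[:space:]]+(", paste(suffixes, collapse = "|"), ")$")
  repeat {
    y <- sub(pat, "", x)
    if (identical(y, x)) break
    x <- y
  }
  x
}

# TRUE for strings that are exactly 8 digits and parse as a calendar-ish date
is_full_fda_dt <- function(x) {
  !is.na(x) & grepl("^[0-9]{8}$", x)
}

# sortable key for FDA receipt dates: full YYYYMMDD dates compare by value;
# partial (YYYY, YYYYMM) or missing dates sort before any full date
fda_date_key <- function(x) {
  x <- as.character(x)
  key <- rep(-1L, length(x))
  full <- is_full_fda_dt(x)
  key[full] <- as.integer(x[full])
  key
}

# first calendar day of a quarter label like "2004Q1", as Date
quarter_start_date <- function(label) {
  stopifnot(all(grepl("^[0-9]{4}Q[1-4]$", label)))
  yr <- substr(label, 1, 4)
  mo <- c("01", "04", "07", "10")[as.integer(substr(label, 6, 6))]
  as.Date(paste(yr, mo, "01", sep = "-"))
}

#' Sequence of quarter labels between two quarters
#'
#' @param from,to quarter labels like `"2004Q1"`.
#' @return character vector of consecutive quarter labels, inclusive.
#' @export
#' @examples
#' quarter_seq("2023Q3", "2024Q1")
quarter_seq <- function(from, to) {
  stopifnot(grepl("^[0-9]{4}Q[1-4]$", from), grepl("^[0-9]{4}Q[1-4]$", to))
  idx <- function(q) as.integer(substr(q, 1, 4)) * 4L + as.integer(substr(q, 6, 6)) - 1L
  if (idx(from) > idx(to)) stop("quarter range is not well-ordered: ", from, " > ", to)
  ii <- idx(from):idx(to)
  sprintf("%dQ%d", ii %/% 4L, ii %% 4L + 1L)
}
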