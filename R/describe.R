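# Descriptive stratifications of a case set: age bands, sex, reporter type,
# country, event year and outcome severity, with percentages of total cases
# rounded half-up to 2 decimals. The percentage denominator is always the
# total case count, including records with unknown values, so single-valued
# dimensions sum to 100% while multi-valued ones (outcome) may exceed it.

age_band_labels <- function() c("≤17", "18-65", "66-85", "≥86", "unknown")

#' Assign an age in years to a reporting band
#'
#' Bands partition the non-negative ages: `[0, 18)` is `"≤17"`,
#' `[18, 66)` is `"18-65"`, `[66, 86)` is `"66-85"`, `[86, Inf)` is
#' `"≥86"`. Missing ages map to `"unknown"`; negative ages map to
#' `"unknown"` with a warning.
#'
#' @param age_years numeric vector of ages in years (may contain `NA`).
#' @return character vector of band labels.
#' @export
band_age <- function(age_years) {
  age_years <- as.numeric(age_years)
  out <- rep("unknown", length(age_years))
  neg <- !is.na(age_years) & age_years < 0
  if (any(neg)) {
    warning(sum(neg), " negative age(s) treated as unknown")
  }
  ok <- !is.na(age_years) & age_years >= 0
  lab <- age_band_labels()
  out[ok & age_years < 18] <- lab[1]
  out[ok & age_years >= 18 & age_years < 66] <- lab[2]
  out[ok & age_years >= 66 & age_years < 86] <- lab[3]
  out[ok & age_years >= 86] <- lab[4]
  out
}

#' Percentage of total, rounded half-up to 2 decimals
#'
#' @param count non-negative integer count(s).
#' @param total positive total.
#' @return `round_half_up(100 * count / total, 2)`.
#' @export
#' @examples
#' percentage(16219, 38307)  # 42.34
percentage <- function(count, total) {
  if (length(total) != 1 || is.na(total) || total <= 0) {
    stop("total must be a single positive number")
  }
  if (any(count < 0, na.rm = TRUE)) stop("counts must be non-negative")
  round_half_up(100 * count / total, 2)
}

#' Stratify a case set along one dimension
#'
#' Dimensions `age`, `sex`, `reporter`, `country` and `year` are single
#' valued: every case contributes to exactly one stratum and an explicit
#' `"unknown"` stratum collects missing values, so counts sum to the case
#' total. The `outcome` dimension counts distinct case-outcome pairs (one
#' case may carry several outcome codes), so its counts may exceed the case
#' total. Percentages use the total case count as denominator.
#'
#' @param case_set a `case_set` whose `reports` have been through
#'   [normalize_demo()].
#' @param dimension one of `"age"`, `"sex"`, `"reporter"`, `"country"`,
#'   `"year"`, `"outcome"`.
#' @param outcomes OUTC stream (`primaryid`, `outc_cod`), required for the
#'   `outcome` dimension.
#' @return data frame with columns `stratum`, `count`, `percent`, ordered by
#'   decreasing count (unknown last); attribute `dimension`.
#' @export
stratify <- function(case_set, dimension, outcomes = NULL) {
  stopifnot(inherits(case_set, "case_set"))
  dims <- c("age", "sex", "reporter", "country", "year", "outcome")
  if (!is.character(dimension) || length(dimension) != 1 ||
      !dimension %in% dims) {
    stop("unknown dimension; use one of: ", paste(dims, collapse = ", "))
  }
  total <- length(case_set$case_ids)
  if (total == 0) {
    return(structure(data.frame(stratum = character(), count = integer(),
                                percent = numeric()),
                     dimension = dimension))
  }
  rep_df <- case_set$reports
  need_col <- function(col) {
    if (!col %in% names(rep_df)) {
      stop("case reports lack the '", col,
           "' column; run normalize_demo() on the DEMO stream first")
    }
    rep_df[[col]]
  }
  if (dimension == "outcome") {
    if (is.null(outcomes)) stop("the outcome dimension needs the OUTC stream")
    oc <- outcomes[as.character(outcomes$primaryid) %in% case_set$case_ids,
                   c("primaryid", "outc_cod"), drop = FALSE]
    oc <- unique(data.frame(primaryid = as.character(oc$primaryid),
                            code = toupper(as.character(oc$outc_cod)),
                            stringsAsFactors = FALSE))
    vals <- oc$code
  } else {
    vals <- switch(dimension,
      age = band_age(need_col("age_years")),
      sex = as.character(need_col("sex")),
      reporter = toupper(as.character(need_col("occp_cod"))),
      country = as.character(need_col("country")),
      year = as.character(need_col("event_year")))
    vals[is.na(vals) | !nzchar(vals)] <- "unknown"
  }
  tab <- table(vals)
  out <- data.frame(stratum = as.character(names(tab)),
                    count = as.integer(tab), stringsAsFactors = FALSE)
  out$percent <- percentage(out$count, total)
  unk <- out$stratum == "unknown"
  out <- rbind(out[!unk, , drop = FALSE][order(-out$count[!unk],
                                               out$stratum[!unk]), ,
                                         drop = FALSE],
               out[unk, , drop = FALSE])
  rownames(out) <- NULL
  structure(out, dimension = dimension, total_cases = total)
}

#' Yearly trend of case reports
#'
#' Counts cases by event year; when the event date is missing the year of
#' the FDA receipt date is used; when both are missing the case is counted
#' under `"unknown"`.
#'
#' @param case_set a `case_set` (reports through [normalize_demo()]).
#' @return data frame with columns `year` (character) and `count`, ordered
#'   by year with `"unknown"` last; empty case set gives zero rows.
#' @export
yearly_trend <- function(case_set) {
  stopifnot(inherits(case_set, "case_set"))
  if (length(case_set$case_ids) == 0) {
    return(data.frame(year = character(), count = integer()))
  }
  rep_df <- case_set$reports
  yr <- as.character(rep_df$event_year %||% rep(NA, nrow(rep_df)))
  fb <- as.character(rep_df$fda_dt)
  use_fb <- is.na(yr) & is_full_fda_dt(fb)
  yr[use_fb] <- substr(fb[use_fb], 1, 4)
  yr[is.na(yr)] <- "unknown"
  tab <- table(yr)
  out <- data.frame(year = as.character(names(tab)),
                    count = as.integer(tab), stringsAsFactors = FALSE)
  unk <- out$year == "unknown"
  out <- rbind(out[!unk, , drop = FALSE][order(out$year[!unk]), ,
                                         drop = FALSE],
               out[unk, , drop = FALSE])
  rownames(out) <- NULL
  out
}
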