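# Duplicate-case collapse.
#
# Spontaneous-report databases receive resubmissions and follow-ups of the
# same case under new report-version ids. The FDA-recommended rule keeps, for
# each CASEID, the report with the most recent FDA receipt date, breaking
# receipt-date ties by the largest PRIMARYID. Deduplication runs globally
# over the pooled set of loaded quarters, not per quarter.

#' Collapse duplicate case submissions to one report per case
#'
#' For each distinct `caseid`, keeps the record with the maximal `fda_dt`;
#' ties are broken by the maximal `primaryid`. primaryids are compared as
#' zero-padded strings, which coincides with numeric order for the all-digit
#' ids FAERS assigns (so `"1000" > "999"`). Records whose `fda_dt` is missing
#' or partial (fewer than 8 digits) lose ties against any fully dated record
#' — a conservative recency rule. Records with an empty `caseid` cannot be
#' grouped and are routed to a quarantine stream, never merged.
#'
#' @param demo data frame of raw demographic records; must contain
#'   `primaryid`, `caseid` and `fda_dt` columns.
#' @return object of class `dedup_result`: list with
#'   \describe{
#'     \item{reports}{data frame of kept records, one per caseid, ordered by
#'       caseid; both `caseid` and `primaryid` are unique.}
#'     \item{quarantined}{records with empty caseid.}
#'     \item{log}{one-row data frame: `input_count`, `kept`, `removed`,
#'       `quarantined`.}
#'   }
#' @export
#' @examples
#' demo <- data.frame(primaryid = c("1001", "1000"),
#'                    caseid = c("100", "100"),
#'                    fda_dt = c("20230101", "20230301"))
#' deduplicate(demo)$reports$primaryid  # "1000": newer receipt date wins
deduplicate <- function(demo) {
  stopifnot(is.data.frame(demo))
  req <- c("primaryid", "caseid", "fda_dt")
  if (!all(req %in% names(demo))) {
    stop("demo stream lacks column(s): ",
         paste(setdiff(req, names(demo)), collapse = ", "))
  }
  n_in <- nrow(demo)
  cid <- as.character(demo$caseid)
  quarantine <- is.na(cid) | trimws(cid) == ""
  q_df <- demo[quarantine, , drop = FALSE]
  d <- demo[!quarantine, , drop = FALSE]

  if (nrow(d) > 0) {
    cid <- as.character(d$caseid)
    pid <- as.character(d$primaryid)
    date_key <- fda_date_key(d$fda_dt)
    w <- max(nchar(pid))
    pid_key <- paste0(strrep("0", w - nchar(pid)), pid)
    ord <- order(cid, date_key, pid_key, method = "radix")
    keep <- !duplicated(cid[ord], fromLast = TRUE)
    kept <- d[ord[keep], , drop = FALSE]
  } else {
    kept <- d
  }
  rownames(kept) <- NULL
  rownames(q_df) <- NULL
  log <- data.frame(input_count = n_in,
                    kept = nrow(kept),
                    removed = n_in - nrow(kept) - nrow(q_df),
                    quarantined = nrow(q_df))
  structure(list(reports = kept, quarantined = q_df, log = log),
            class = "dedup_result")
}

#' @export
print.dedup_result <- function(x, ...) {
  cat("Deduplication:", x$log$input_count, "reports in,",
      x$log$kept, "kept,", x$log$removed, "removed,",
      x$log$quarantined, "quarantined\n")
  invisible(x)
}

#' Write a deduplication log as CSV
#'
#' @param x a `dedup_result`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_dedup_log <- function(x, path) {
  stopifnot(inherits(x, "dedup_result"))
  utils::write.csv(x$log, path, row.names = FALSE)
  invisible(path)
}
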