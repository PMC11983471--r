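# Disproportionality analysis: per-drug 2x2 tables against the deduplicated
# background, reporting odds ratios with Woolf 95% confidence intervals, the
# a>=3 & CI-lower-bound>1 signal rule, ranking, and label-gap flagging.
#
# For drug X and target event E over N deduplicated reports:
#            event E    no E
#   drug X      a         b
#   no X        c         d
# ROR = (a*d)/(b*c); 95% CI = exp(log ROR +/- 1.96 * sqrt(1/a+1/b+1/c+1/d)).
# The unit of counting is the report: a drug mentioned several times in one
# report, or an event coded twice, contributes once.

#' Build per-drug 2x2 contingency tables
#'
#' One table per generic with at least one case report (`a >= 1`). Marginals
#' satisfy `a + c = case count`, `a + b = reports mentioning the drug`,
#' `a + b + c + d = N` (deduplicated background).
#'
#' @param case_set a `case_set` from [extract_cases()], or a character vector
#'   of case primaryids.
#' @param reports the deduplicated report data frame (the background
#'   universe). Every case id must be present in it.
#' @param mentions normalized drug mentions from [normalize_mentions()];
#'   mentions referencing reports outside the universe (superseded report
#'   versions) are dropped, with their count in the `orphan_mentions`
#'   attribute.
#' @return data frame with columns `drug`, `a`, `b`, `c`, `d`, `n`, one row
#'   per drug, ordered by drug name.
#' @export
build_contingency <- function(case_set, reports, mentions) {
  ids <- if (inherits(case_set, "case_set")) case_set$case_ids
         else as.character(case_set)
  pid_all <- as.character(reports$primaryid)
  missing_ids <- setdiff(ids, pid_all)
  if (length(missing_ids) > 0) {
    stop("mismatched universes: ", length(missing_ids),
         " case id(s) absent from the report set (e.g. ",
         missing_ids[1], ")")
  }
  m_pid <- as.character(mentions$primaryid)
  in_univ <- m_pid %in% pid_all
  m <- data.frame(primaryid = m_pid[in_univ],
                  generic = as.character(mentions$generic)[in_univ],
                  stringsAsFactors = FALSE)
  m <- m[!duplicated(m), , drop = FALSE]

  N <- nrow(reports)
  n_case <- length(ids)
  is_case <- m$primaryid %in% ids
  gen <- sort(unique(m$generic))
  tot <- as.integer(table(factor(m$generic, levels = gen)))
  a <- as.integer(table(factor(m$generic[is_case], levels = gen)))
  out <- data.frame(drug = gen, a = a, b = tot - a, c = n_case - a,
                    d = N - tot - (n_case - a), n = N,
                    stringsAsFactors = FALSE)
  out <- out[out$a >= 1, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "orphan_mentions") <- sum(!in_univ)
  out
}

#' Reporting odds ratio with Woolf 95% confidence interval
#'
#' `ROR = (a*d)/(b*c)` with
#' `CI95 = exp(log(ROR) +/- 1.96 * sqrt(1/a + 1/b + 1/c + 1/d))`.
#' A drug is flagged as a signal when `a >= min_a` and the CI lower bound
#' exceeds 1. Tables with any zero cell have an undefined estimate (no
#' signal) unless the Haldane-Anscombe continuity correction is enabled, in
#' which case 0.5 is added to all four cells of those tables and the result
#' is flagged `corrected`. Reported values are unrounded; round only for
#' presentation.
#'
#' @param tables data frame with columns `a`, `b`, `c`, `d` (and optionally
#'   `drug`), e.g. from [build_contingency()].
#' @param continuity `"off"` (default) or `"on"`.
#' @param min_a minimum case count for the signal rule (default 3).
#' @return the input with columns `ror`, `ci_low`, `ci_high`, `signal`,
#'   `undefined`, `corrected` added.
#' @export
#' @examples
#' ror(data.frame(a = 10, b = 90, c = 100, d = 9900))
ror <- function(tables, continuity = c("off", "on"), min_a = 3) {
  continuity <- match.arg(continuity)
  stopifnot(all(c("a", "b", "c", "d") %in% names(tables)))
  a0 <- as.numeric(tables$a)
  b <- as.numeric(tables$b)
  cc <- as.numeric(tables$c)
  d <- as.numeric(tables$d)
  if (any(c(a0, b, cc, d) < 0, na.rm = TRUE)) stop("negative cell counts")
  zero <- a0 == 0 | b == 0 | cc == 0 | d == 0
  corrected <- rep(FALSE, length(a0))
  a <- a0
  if (continuity == "on" && any(zero)) {
    a[zero] <- a0[zero] + 0.5
    b[zero] <- b[zero] + 0.5
    cc[zero] <- cc[zero] + 0.5
    d[zero] <- d[zero] + 0.5
    corrected <- zero
    zero <- rep(FALSE, length(a0))
  }
  z <- 1.96
  est <- (a * d) / (b * cc)
  se <- sqrt(1 / a + 1 / b + 1 / cc + 1 / d)
  lo <- exp(log(est) - z * se)
  hi <- exp(log(est) + z * se)
  est[zero] <- lo[zero] <- hi[zero] <- NA_real_

  out <- tables
  out$ror <- est
  out$ci_low <- lo
  out$ci_high <- hi
  out$undefined <- zero
  out$corrected <- corrected
  out$signal <- !zero & !is.na(lo) & a0 >= min_a & lo > 1
  out
}

#' Rank drugs by case-report frequency
#'
#' Descending by `a` (the drug-and-event report count), ties broken
#' alphabetically by drug name.
#'
#' @param results data frame with `drug` and `a` columns.
#' @param n maximum number of drugs to keep (e.g. 50).
#' @return the top `min(n, nrow(results))` rows, re-ordered.
#' @export
rank_drugs <- function(results, n) {
  stopifnot(is.numeric(n), n >= 1)
  ord <- order(-results$a, results$drug, method = "radix")
  out <- results[ord[seq_len(min(n, nrow(results)))], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Flag label gaps among signal-positive drugs
#'
#' Annotates each drug with whether the target event is a known on-label
#' risk. Signal-positive drugs absent from the risk list (or listed as not
#' at risk) are potential new signals.
#'
#' @param results data frame with `drug` and `signal` columns (from [ror()]).
#' @param risk_list data frame from [read_label_risk()].
#' @return the input with `risk_on_label` and `label_status`
#'   (`"known-risk"` / `"potential-new-signal"` / `"no-signal"`) added;
#'   attribute `label_gap_counts` holds the summary counts.
#' @export
flag_label_gaps <- function(results, risk_list) {
  idx <- match(results$drug, risk_list$generic)
  risk <- !is.na(idx) & risk_list$risk_on_label[idx]
  status <- ifelse(results$signal,
                   ifelse(risk, "known-risk", "potential-new-signal"),
                   "no-signal")
  out <- results
  out$risk_on_label <- risk
  out$label_status <- status
  attr(out, "label_gap_counts") <- c(
    signals = sum(results$signal),
    known_risk = sum(status == "known-risk"),
    potential_new_signal = sum(status == "potential-new-signal"))
  out
}

#' Write a ROR results table as CSV
#'
#' ROR and CI columns are rounded half-up to 2 decimals for presentation;
#' the in-memory results stay unrounded.
#'
#' @param results data frame from [ror()] (optionally annotated).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_ror_table <- function(results, path) {
  out <- results
  for (nm in intersect(c("ror", "ci_low", "ci_high"), names(out))) {
    out[[nm]] <- round_half_up(out[[nm]], 2)
  }
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}
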