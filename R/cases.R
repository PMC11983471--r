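# Case extraction for a target MedDRA preferred term.

#' Extract the case set for a target preferred term
#'
#' A deduplicated report is a case iff any of its reaction rows matches the
#' target: preferred-term names are compared case-insensitively after
#' whitespace trimming/collapsing (exact match, not substring), codes by
#' numeric equality. A report is counted once however many matching reaction
#' rows it carries. Reaction rows whose primaryid is not in the deduplicated
#' report set belong to superseded report versions and are ignored.
#'
#' @param reports deduplicated report data frame (e.g.
#'   `deduplicate(...)$reports`).
#' @param reactions REAC stream with `primaryid` and `pt` (optionally
#'   `pt_cod`) columns.
#' @param pt character vector of target preferred-term names (one or more).
#' @param pt_code optional numeric vector of MedDRA PT codes; a row matches
#'   on name or code.
#' @return object of class `case_set`: list with `target_pt`, `target_code`,
#'   `case_ids` (primaryids, unique), `reports` (demographic rows of the
#'   cases) and `n_background` (deduplicated report count).
#' @export
extract_cases <- function(reports, reactions, pt = NULL, pt_code = NULL) {
  has_pt <- !is.null(pt) && any(nzchar(trimws(pt)))
  if (!has_pt && is.null(pt_code)) {
    stop("a target preferred term ('pt') or code ('pt_code') is required")
  }
  stopifnot(is.data.frame(reports), is.data.frame(reactions))
  bg_ids <- as.character(reports$primaryid)
  rx <- reactions[as.character(reactions$primaryid) %in% bg_ids, , drop = FALSE]

  hit <- rep(FALSE, nrow(rx))
  if (has_pt) {
    targets <- tolower(squish(pt))
    targets <- targets[nzchar(targets)]
    hit <- tolower(squish(as.character(rx$pt))) %in% targets
  }
  if (!is.null(pt_code) && "pt_cod" %in% names(rx)) {
    codes <- suppressWarnings(as.numeric(rx$pt_cod))
    hit <- hit | (!is.na(codes) & codes %in% as.numeric(pt_code))
  }
  ids <- unique(as.character(rx$primaryid[hit]))
  structure(list(target_pt = pt, target_code = pt_code, case_ids = ids,
                 reports = reports[bg_ids %in% ids, , drop = FALSE],
                 n_background = nrow(reports)),
            class = "case_set")
}

#' @export
print.case_set <- function(x, ...) {
  cat("Case set for PT",
      paste(sQuote(x$target_pt), collapse = ", "),
      if (!is.null(x$target_code)) paste0("(code ", x$target_code, ")"), "\n")
  cat(" ", length(x$case_ids), "cases out of", x$n_background,
      "deduplicated reports\n")
  invisible(x)
}

#' Case-level joined table (one row per case x drug mention)
#'
#' @param case_set a `case_set`.
#' @param mentions normalized drug mentions (see [normalize_mentions()]).
#' @return data frame joining case demographics to their drug mentions;
#'   cases without any mention appear once with `generic = NA`.
#' @export
case_drug_table <- function(case_set, mentions) {
  stopifnot(inherits(case_set, "case_set"))
  m <- mentions[as.character(mentions$primaryid) %in% case_set$case_ids,
                c("primaryid", "generic"), drop = FALSE]
  out <- merge(case_set$reports, m, by = "primaryid", all.x = TRUE,
               sort = TRUE)
  rownames(out) <- NULL
  out
}
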