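# Drug-name normalization and annotation.
#
# Verbatim names in spontaneous reports mix brands, generics, dosages and
# typography. Normalization here is dictionary-driven: keys are normalized
# with norm_key() (lowercase, squeeze whitespace, strip trailing dosage/form
# tokens) and looked up in a user-auditable two/three-column table. A starter
# dictionary and an illustrative label-risk list ship under
# inst/extdata/ (synthetic starter files, meant to be replaced by the
# analyst's own curated tables).

#' Read a drug-name normalization dictionary
#'
#' CSV with columns `verbatim`, `generic` and optionally `atc`. Keys are
#' normalized with [norm_key()]; duplicate keys mapping to different generics
#' are an error. Identity entries (`generic` mapping to itself) are added for
#' every generic so that [normalize_name()] is idempotent on its outputs.
#' A `generic` field containing `+` denotes a combination product; it is
#' expanded to its component generics by [normalize_mentions()].
#'
#' @param path CSV file path.
#' @param suffixes trailing-token patterns passed to [norm_key()].
#' @return data frame with columns `key`, `generic`, `atc`.
#' @export
read_drug_dictionary <- function(path, suffixes = default_dose_suffixes()) {
  if (!file.exists(path)) stop("drug dictionary not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(raw) <- tolower(names(raw))
  if (!all(c("verbatim", "generic") %in% names(raw))) {
    stop("drug dictionary needs 'verbatim' and 'generic' columns")
  }
  if (any(is.na(raw$generic) | !nzchar(trimws(raw$generic)))) {
    stop("drug dictionary contains empty generic names")
  }
  dict <- data.frame(key = norm_key(raw$verbatim, suffixes),
                     generic = squish(raw$generic),
                     atc = if ("atc" %in% names(raw)) squish(raw$atc)
                           else rep(NA_character_, nrow(raw)),
                     stringsAsFactors = FALSE)
  dict <- unique(dict[, c("key", "generic", "atc")])
  dup <- duplicated(dict$key)
  if (any(dup)) {
    stop("conflicting dictionary entries for key(s): ",
         paste(unique(dict$key[dup]), collapse = ", "))
  }
  # identity entries keep normalization idempotent
  gen <- unique(dict$generic)
  gen_single <- gen[!grepl("+", gen, fixed = TRUE)]
  miss <- !norm_key(gen_single, suffixes) %in% dict$key
  if (any(miss)) {
    add <- data.frame(key = norm_key(gen_single[miss], suffixes),
                      generic = gen_single[miss],
                      atc = dict$atc[match(gen_single[miss], dict$generic)],
                      stringsAsFactors = FALSE)
    add <- add[!duplicated(add$key), , drop = FALSE]
    dict <- rbind(dict, add)
  }
  rownames(dict) <- NULL
  attr(dict, "suffixes") <- suffixes
  dict
}

#' Path to the packaged starter dictionary / label-risk list
#'
#' Small illustrative files covering a few dozen well-known generics and
#' brands; real analyses should supply curated tables.
#'
#' @name starter-files
#' @return a file path.
#' @export
starter_drug_dictionary <- function() {
  system.file("extdata", "drug_dictionary_starter.csv", package = "pvsignal",
              mustWork = TRUE)
}

#' @rdname starter-files
#' @export
starter_label_risk <- function() {
  system.file("extdata", "label_risk_starter.csv", package = "pvsignal",
              mustWork = TRUE)
}

#' Normalize verbatim drug names against a dictionary
#'
#' Total function: a dictionary hit returns the mapped generic with
#' `matched = TRUE`; a miss returns the normalized verbatim key with
#' `matched = FALSE` (names are never dropped silently).
#'
#' @param verbatim character vector of verbatim drug names.
#' @param dict dictionary from [read_drug_dictionary()].
#' @return data frame with columns `verbatim`, `generic`, `matched`; the
#'   `match_rate` attribute gives the fraction matched.
#' @export
#' @examples
#' dict <- read_drug_dictionary(starter_drug_dictionary())
#' normalize_name(c("HUMIRA  40MG", "zzz-unknown-drug"), dict)
normalize_name <- function(verbatim, dict) {
  key <- norm_key(as.character(verbatim), attr(dict, "suffixes") %||%
                    default_dose_suffixes())
  idx <- match(key, dict$key)
  matched <- !is.na(idx)
  generic <- ifelse(matched, dict$generic[idx], key)
  out <- data.frame(verbatim = as.character(verbatim), generic = generic,
                    matched = matched, stringsAsFactors = FALSE)
  attr(out, "match_rate") <- if (nrow(out) > 0) mean(matched) else NA_real_
  out
}

#' Normalize a DRUG mention stream
#'
#' Applies [normalize_name()] to every mention, expands combination products
#' (dictionary generics containing `+`) into one row per component (flagged
#' `combination = TRUE`), and collapses multiple mentions of the same generic
#' within one report into a single drug-per-report occurrence, so 2x2 counts
#' are per report.
#'
#' @param drug DRUG stream with `primaryid` and `drugname` columns
#'   (optionally `role_cod`).
#' @param dict dictionary from [read_drug_dictionary()].
#' @param roles optional character vector of role codes to keep (e.g.
#'   `c("PS", "SS")`); `NULL` keeps all mentions.
#' @return data frame with columns `primaryid`, `generic`, `matched`,
#'   `combination`, one row per (report, generic) pair. Attributes:
#'   `match_rate`, `n_mentions_in`.
#' @export
normalize_mentions <- function(drug, dict, roles = NULL) {
  stopifnot(is.data.frame(drug))
  d <- drug
  if (!is.null(roles)) {
    if (!"role_cod" %in% names(d)) stop("no role_cod column to filter on")
    d <- d[toupper(as.character(d$role_cod)) %in% toupper(roles), ,
           drop = FALSE]
  }
  n_in <- nrow(d)
  nn <- normalize_name(d$drugname, dict)
  out <- data.frame(primaryid = as.character(d$primaryid),
                    generic = nn$generic, matched = nn$matched,
                    combination = FALSE, stringsAsFactors = FALSE)
  combo <- grepl("+", out$generic, fixed = TRUE)
  if (any(combo)) {
    parts <- strsplit(out$generic[combo], "[[:space:]]*\\+[[:space:]]*")
    expanded <- data.frame(
      primaryid = rep(out$primaryid[combo], lengths(parts)),
      generic = unlist(parts),
      matched = rep(out$matched[combo], lengths(parts)),
      combination = TRUE, stringsAsFactors = FALSE)
    out <- rbind(out[!combo, , drop = FALSE], expanded)
  }
  collapsed <- out[!duplicated(out[, c("primaryid", "generic")]), ,
                   drop = FALSE]
  rownames(collapsed) <- NULL
  attr(collapsed, "match_rate") <- attr(nn, "match_rate")
  attr(collapsed, "n_mentions_in") <- n_in
  collapsed
}

#' Assign an ATC class label to generic names
#'
#' Precedence: dictionary ATC entry, then the manual fallback map, then
#' `"unclassified"`.
#'
#' @param generic character vector of generic names.
#' @param dict dictionary from [read_drug_dictionary()].
#' @param fallback optional named character vector, `generic -> class label`.
#' @return character vector of class labels.
#' @export
assign_atc <- function(generic, dict, fallback = NULL) {
  stopifnot(all(nzchar(generic)))
  idx <- match(generic, dict$generic)
  out <- dict$atc[idx]
  if (!is.null(fallback)) {
    use_fb <- (is.na(out) | !nzchar(out)) & generic %in% names(fallback)
    out[use_fb] <- fallback[generic[use_fb]]
  }
  out[is.na(out) | !nzchar(out)] <- "unclassified"
  out
}

#' Read a label-risk list
#'
#' CSV with columns `generic` and `risk_on_label` (logical, or yes/no).
#'
#' @param path CSV file path.
#' @return data frame with columns `generic`, `risk_on_label` (logical).
#' @export
read_label_risk <- function(path) {
  if (!file.exists(path)) stop("label-risk list not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(raw) <- tolower(names(raw))
  if (!all(c("generic", "risk_on_label") %in% names(raw))) {
    stop("label-risk list needs 'generic' and 'risk_on_label' columns")
  }
  risk <- tolower(trimws(as.character(raw$risk_on_label)))
  out <- data.frame(generic = squish(raw$generic),
                    risk_on_label = risk %in% c("true", "t", "yes", "y", "1"),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$generic)) {
    stop("duplicate generic names in label-risk list")
  }
  out
}
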